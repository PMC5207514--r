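test_that("generator reproduces requested class sizes and motif structure", {
  spec <- synthetic_spec(seed = 12)
  d <- generate_synthetic(spec)
  expect_identical(nrow(d$records), 266L)
  expect_identical(sum(d$labels == 1L), 90L)
  expect_identical(sum(d$labels == -1L), 176L)

  tri <- substr(d$records$seq, nchar(d$records$seq) - 2, nchar(d$records$seq))
  expect_true(all(tri[d$labels == 1L] %in% spec$motifs))
  expect_false(any(tri[d$labels == -1L] %in% spec$motifs))

  lens <- nchar(d$records$seq)
  expect_true(all(lens >= spec$length_range[1] & lens <= spec$length_range[2]))
})

test_that("generation is byte-identical across runs with the same seed", {
  spec <- synthetic_spec(n_pos = 15, n_neg = 30, seed = 77)
  d1 <- generate_synthetic(spec)
  d2 <- generate_synthetic(spec)
  expect_identical(d1, d2)

  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset_fasta(d1, dir1)
  write_dataset_fasta(d2, dir2)
  for (f in c("positive.fa", "negative.fa")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  d3 <- generate_synthetic(synthetic_spec(n_pos = 15, n_neg = 30, seed = 78))
  expect_false(identical(d1$records$seq, d3$records$seq))
})

test_that("positive termini are uniform over the motif set", {
  spec <- synthetic_spec(n_pos = 6000, n_neg = 1, seed = 5)
  d <- generate_synthetic(spec)
  pos <- d$records$seq[d$labels == 1L]
  tri <- substr(pos, nchar(pos) - 2, nchar(pos))
  tab <- table(factor(tri, levels = spec$motifs))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("biased positions carry the enriched residue at the stated weight", {
  spec <- synthetic_spec(n_pos = 4000, n_neg = 1, seed = 6)
  d <- generate_synthetic(spec)
  w <- cterm_windows(d$records[d$labels == 1L, ], L = spec$L)
  for (i in seq_along(spec$biased_positions)) {
    p <- mean(w[, as.character(spec$biased_positions[i])] ==
              spec$enriched_residues[i])
    # enrichment plus the background's own share of that residue
    expected <- spec$enrichment + (1 - spec$enrichment) / 20
    expect_equal(p, expected, tolerance = 0.035)
  }
})

test_that("spec validation rejects impossible settings", {
  expect_error(synthetic_spec(n_pos = 0), ">= 1")
  expect_error(synthetic_spec(enrichment = 0), "enrichment")
  expect_error(synthetic_spec(motifs = "SKLX"), "tripeptides")
  expect_error(synthetic_spec(biased_positions = 0L), "-\\(L-1\\)")
  expect_error(synthetic_spec(length_range = c(10L, 50L)), ">= L")
})

test_that("greedy redundancy filter matches the brute-force identity oracle", {
  # two identical sequences: one kept
  recs <- data.frame(id = c("a", "b"), desc = "",
                     seq = c("MASKLQWERTY", "MASKLQWERTY"))
  expect_identical(redundancy_filter(recs, 0.9, L = 10)$id, "a")

  # all-distinct windows survive threshold 1.0
  set.seed(31)
  distinct <- data.frame(id = paste0("d", 1:6), desc = "", seq = vapply(1:6,
    function(i) paste(sample(aa_alphabet(FALSE), 12, TRUE), collapse = ""),
    character(1)))
  expect_identical(nrow(redundancy_filter(distinct, 1.0, L = 12)), 6L)

  # 10 records in 3 exact-duplicate groups collapse to 3
  base <- vapply(1:3, function(i)
    paste(sample(aa_alphabet(FALSE), 15, TRUE), collapse = ""), character(1))
  grp <- data.frame(id = paste0("g", 1:10), desc = "",
                    seq = base[c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)])
  kept <- redundancy_filter(grp, 0.95, L = 15)
  expect_identical(nrow(kept), 3L)
  # oracle: kept records are mutually below threshold, dropped ones are not
  im <- identity_matrix(grp, L = 15)
  kept_idx <- match(kept$id, grp$id)
  off <- im[kept_idx, kept_idx]
  expect_true(all(off[lower.tri(off)] < 0.95))
  for (i in setdiff(1:10, kept_idx)) {
    expect_true(any(im[i, kept_idx[kept_idx < i]] >= 0.95))
  }
  expect_error(redundancy_filter(grp, 1.5), "0, 1")
})

test_that("dataset assembly concatenates classes and rejects id collisions", {
  spec <- synthetic_spec(n_pos = 9, n_neg = 19, seed = 2)
  parts <- split_dataset(generate_synthetic(spec))
  ds <- assemble_dataset(parts$pos, parts$neg)
  expect_identical(nrow(ds$records), 28L)
  expect_identical(ds$labels, rep(c(1L, -1L), c(9L, 19L)))
  expect_identical(ds$records$id, c(parts$pos$id, parts$neg$id))

  clash <- parts$neg
  clash$id[1] <- parts$pos$id[1]
  expect_error(assemble_dataset(parts$pos, clash), "both classes")
  expect_error(assemble_dataset(parts$pos[0, ], parts$neg), "non-empty")
})

test_that("models trained on one synthetic cohort transfer to an independent one", {
  tr <- split_dataset(generate_synthetic(synthetic_spec(seed = 501)))
  te <- split_dataset(generate_synthetic(synthetic_spec(seed = 502)))
  fit <- pts1_svm(tr$pos, tr$neg)
  pred <- predict(fit, rbind(te$pos, te$neg), cutoff = 0)
  truth <- rep(c(1L, -1L), c(nrow(te$pos), nrow(te$neg)))
  m <- compute_metrics(confusion_counts(pred$label, truth))
  expect_gte(m$sensitivity, 0.9)
  expect_gte(m$specificity, 0.9)
})
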