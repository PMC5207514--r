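test_that("metric formulas reproduce known confusion matrices", {
  m <- compute_metrics(c(TP = 75, FP = 2, TN = 174, FN = 15))
  expect_equal(as.numeric(format3(m$accuracy)), 0.936)
  expect_equal(as.numeric(format3(m$mcc)), 0.858)

  m2 <- compute_metrics(c(TP = 90, FP = 175, TN = 1, FN = 0))
  expect_equal(as.numeric(format3(m2$accuracy)), 0.342)
  expect_equal(as.numeric(format3(m2$mcc)), 0.044)

  perfect <- compute_metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$mcc, 1)
})

test_that("degenerate confusions give NA rates and an undefined-MCC flag, not errors", {
  m <- compute_metrics(c(TP = 0, FP = 196, TN = 0, FN = 0))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$mcc))
  expect_true(m$mcc_undefined)
  expect_match(format3(m$mcc), "N.A.", fixed = TRUE)
  expect_error(compute_metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
})

test_that("metric identities hold for arbitrary confusions", {
  set.seed(21)
  for (i in 1:50) {
    cts <- c(TP = sample(0:80, 1), FP = sample(0:80, 1),
             TN = sample(0:80, 1), FN = sample(0:80, 1))
    if (sum(cts) == 0) next
    m <- compute_metrics(cts)
    P <- cts["TP"] + cts["FN"]; N <- cts["TN"] + cts["FP"]
    if (P > 0 && N > 0) {
      expect_equal(m$accuracy,
                   unname((m$sensitivity * P + m$specificity * N) / (P + N)),
                   tolerance = 1e-12)
    }
    # MCC is invariant under the TP<->TN, FP<->FN swap
    sw <- compute_metrics(c(TP = cts[["TN"]], FP = cts[["FN"]],
                            TN = cts[["TP"]], FN = cts[["FP"]]))
    if (!m$mcc_undefined) expect_equal(m$mcc, sw$mcc, tolerance = 1e-12)
  }
})

test_that("confusion reconstruction inverts printed rates to integer counts", {
  expect_identical(reconstruct_confusion(0.833, 0.987, 90, 176),
                   c(TP = 75L, FP = 2L, TN = 174L, FN = 15L))
  expect_identical(reconstruct_confusion(1.0, 0.006, 90, 176),
                   c(TP = 90L, FP = 175L, TN = 1L, FN = 0L))
  expect_identical(reconstruct_confusion(1, 1, 5, 5),
                   c(TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  expect_error(reconstruct_confusion(1.2, 0.5, 10, 10), "\\[0, 1\\]")

  # enumeration oracle: the rounded TP is the integer minimizing |TP/P - sens|
  set.seed(33)
  for (i in 1:30) {
    P <- sample(5:200, 1); N <- sample(5:200, 1)
    sens <- round(runif(1), 3); spec <- round(runif(1), 3)
    got <- reconstruct_confusion(sens, spec, P, N)
    best_tp <- which.min(abs((0:P) / P - sens)) - 1L
    best_tn <- which.min(abs((0:N) / N - spec)) - 1L
    expect_identical(unname(got["TP"]), best_tp)
    expect_identical(unname(got["TN"]), best_tn)
  }
})

test_that("cutoff sweep rows follow the threshold monotonicity laws", {
  set.seed(9)
  scores <- c(rnorm(40, 1.5), rnorm(80, -1.5))
  labels <- rep(c(1L, -1L), c(40, 80))
  tab <- cutoff_sweep(scores, labels)
  expect_identical(tab$cutoff, seq(-1.5, 1.5, by = 0.5))
  expect_true(all(diff(tab$sensitivity) <= 1e-12))
  expect_true(all(diff(tab$specificity) >= -1e-12))
  # raising the cutoff never increases positive calls
  expect_true(all(diff(tab$TP + tab$FP) <= 0))
  # a cutoff below every score calls everything positive
  low <- cutoff_sweep(scores, labels, cutoffs = min(scores) - 1)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
  expect_error(cutoff_sweep(scores, labels, cutoffs = numeric(0)), "empty")
})

test_that("cross-validation is deterministic, stratified and pools one confusion", {
  tr <- small_training()
  cv1 <- cv_pts1_svm(tr$pos, tr$neg, cutoff = 0, seed = 5)
  cv2 <- cv_pts1_svm(tr$pos, tr$neg, cutoff = 0, seed = 5)
  expect_identical(cv1$scores, cv2$scores)
  expect_equal(cv1$pooled$counts, cv2$pooled$counts)

  cv3 <- cv_pts1_svm(tr$pos, tr$neg, cutoff = 0, seed = 6)
  expect_false(identical(cv1$scores$fold, cv3$scores$fold))

  # every fold sees both classes and all records are scored exactly once
  for (f in 1:5) {
    held <- cv1$scores[cv1$scores$fold == f, ]
    expect_true(all(c(1L, -1L) %in% held$truth))
  }
  expect_identical(sum(cv1$pooled$counts), nrow(tr$pos) + nrow(tr$neg))
  expect_error(cv_pts1_svm(tr$pos[1:3, ], tr$neg, k = 5), "exceeds class size")
})

test_that("length sweep emits one CV row per window length", {
  tr <- small_training(n_pos = 20, n_neg = 40)
  tab <- length_sweep(tr$pos_records, tr$neg_records,
                      lengths = c(3L, 5L, 10L), k = 3, cutoff = 0,
                      cost = 8, gamma = 0.25, seed = 2)
  expect_identical(tab$L, c(3L, 5L, 10L))
  expect_identical(nrow(tab), 3L)
  # L = 3 uses only the terminal tripeptide, which separates the classes
  expect_gt(tab$accuracy[1], 0.9)
  expect_error(length_sweep(tr$pos_records, tr$neg_records, lengths = 0L),
               ">= 1")
})
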