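# Shared fixture builders. Everything is generated in code at test time.

# A tiny FASTA file on disk; returns its path.
tiny_fasta <- function(entries, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(entries), function(h) {
    c(paste0(">", h), entries[[h]])
  }))
  writeLines(lines, path)
  path
}

# Window matrix straight from short sequences (no padding when nchar == L).
windows_of <- function(seqs, L = nchar(seqs[1])) {
  cterm_windows(clean_sequence(seqs), L = L)
}

# Small, clearly separable two-class training set for model tests.
small_training <- function(n_pos = 30, n_neg = 60, seed = 101, L = 12) {
  spec <- synthetic_spec(n_pos = n_pos, n_neg = n_neg, L = L,
                         biased_positions = c(-6L, -5L),
                         enriched_residues = c("A", "R"),
                         length_range = c(L, 4L * L), seed = seed)
  parts <- split_dataset(generate_synthetic(spec))
  list(pos = cterm_windows(parts$pos, L), neg = cterm_windows(parts$neg, L),
       pos_records = parts$pos, neg_records = parts$neg)
}

# Independent oracle for the naive-Bayes log-odds: multiply raw
# probabilities directly and take one log of the ratio at the end.
nb_oracle <- function(window_chars, pair) {
  p1 <- pair$priors[["pos"]]
  p0 <- pair$priors[["neg"]]
  for (i in seq_along(window_chars)) {
    p1 <- p1 * pair$positive$prob[i, window_chars[i]]
    p0 <- p0 * pair$negative$prob[i, window_chars[i]]
  }
  log(p1 / p0)
}

# Brute-force pairwise identity matrix used to check the greedy
# redundancy filter on small inputs.
identity_matrix <- function(records, L) {
  w <- cterm_windows(records, L)
  n <- nrow(w)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- mean(w[i, ] == w[j, ])
  }
  m
}
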