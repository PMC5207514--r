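#' Position-specific amino-acid probability profile
#'
#' Estimates, for one class of training windows, the probability of each
#' alphabet symbol at each window position: the position-specific
#' occurrence f(a at i) / m_i, optionally Laplace-smoothed. With
#' pseudocount `alpha` the estimate at position i is
#' `(count(a, i) + alpha) / (m_i + 21 * alpha)` over the 21-symbol
#' alphabet, so every entry is strictly positive when `alpha > 0`.
#'
#' @param windows character matrix of aligned windows ([cterm_windows()]).
#' @param alpha non-negative pseudocount; default 1 (Laplace). The model
#'   equations take logs of these probabilities, so `alpha = 0` is only
#'   safe for descriptive use.
#' @param class optional class label stored with the profile.
#' @return An object of class `position_profile`: list with `prob`
#'   (L x 21 matrix, rows are positions and sum to 1), `alpha`, `m`
#'   (windows per position), `L`, `class`.
#' @examples
#' w <- cterm_windows(c("SKL", "AKL"), L = 3)
#' position_profile(w, alpha = 0)$prob["-1", "K"]  # 1
#' @export
position_profile <- function(windows, alpha = 1, class = NA_character_) {
  if (!is.matrix(windows) || nrow(windows) == 0L) {
    stop("'windows' must be a non-empty character matrix")
  }
  if (alpha < 0) stop("pseudocount alpha must be non-negative")
  L <- ncol(windows)
  bad <- setdiff(unique(as.vector(windows)), AA21)
  if (length(bad)) stop("symbols outside the alphabet: ",
                        paste(bad, collapse = ", "))
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(windows[, j], AA21), nbins = 21L)
  }, numeric(21L))
  counts <- t(counts)  # L x 21
  m <- nrow(windows)
  prob <- (counts + alpha) / (m + 21 * alpha)
  dimnames(prob) <- list(position_labels(L), AA21)
  structure(list(prob = prob, counts = counts, alpha = alpha,
                 m = rep.int(m, L), L = L, class = class),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("Position profile: %d positions x %d symbols (class %s, n = %d, alpha = %g)\n",
              x$L, ncol(x$prob), x$class, x$m[1], x$alpha))
  invisible(x)
}

#' Bi-profile pair: positive and negative class profiles
#'
#' Builds the two class-conditional position profiles that define the
#' bi-profile Bayes encoding, plus the class priors P(c1), P(c-1).
#'
#' @param pos_windows,neg_windows window matrices for the peroxisomal
#'   (positive) and non-peroxisomal (negative) training sets; same width.
#' @param alpha pseudocount passed to [position_profile()].
#' @param priors `"empirical"` (class counts / total; the training ratio
#'   is conventionally 1:2) or `"uniform"` (0.5/0.5, for when the class
#'   ratio is a sampling artifact).
#' @return Object of class `bpb_profile_pair`: list with `positive`,
#'   `negative` ([position_profile()]s), `priors` (named, sums to 1),
#'   `L`, `alpha`.
#' @export
profile_pair <- function(pos_windows, neg_windows, alpha = 1,
                         priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  if (!is.matrix(pos_windows) || !is.matrix(neg_windows) ||
      nrow(pos_windows) == 0L || nrow(neg_windows) == 0L) {
    stop("both classes need at least one window")
  }
  if (ncol(pos_windows) != ncol(neg_windows)) {
    stop("positive and negative windows must share the same length")
  }
  n_pos <- nrow(pos_windows)
  n_neg <- nrow(neg_windows)
  p <- if (priors == "empirical") {
    c(pos = n_pos, neg = n_neg) / (n_pos + n_neg)
  } else {
    c(pos = 0.5, neg = 0.5)
  }
  structure(list(positive = position_profile(pos_windows, alpha, "positive"),
                 negative = position_profile(neg_windows, alpha, "negative"),
                 priors = p, L = ncol(pos_windows), alpha = alpha),
            class = "bpb_profile_pair")
}

#' @export
print.bpb_profile_pair <- function(x, ...) {
  cat(sprintf("Bi-profile pair: L = %d, alpha = %g, priors = (%.3f, %.3f), n = (%d, %d)\n",
              x$L, x$alpha, x$priors["pos"], x$priors["neg"],
              x$positive$m[1], x$negative$m[1]))
  invisible(x)
}

# Per-window class-conditional probabilities: n x L matrix of
# P(s_i | class) looked up from one profile.
profile_lookup <- function(windows, profile) {
  L <- profile$L
  if (ncol(windows) != L) {
    stop("window length ", ncol(windows), " does not match profile L = ", L)
  }
  idx <- match(windows, AA21)  # column-major over the window matrix
  pos_idx <- rep(seq_len(L), each = nrow(windows))
  matrix(profile$prob[cbind(pos_idx, idx)], nrow = nrow(windows))
}

#' Bi-profile Bayes feature vectors
#'
#' Encodes each window as a length-2L numeric vector: the per-position
#' probabilities of its residues under the positive-class profile
#' (entries 1..L, in position order -(L-1)..0) followed by the same
#' probabilities under the negative-class profile (entries L+1..2L).
#'
#' @param windows window matrix ([cterm_windows()]).
#' @param pair [profile_pair()] of matching window length.
#' @return Numeric matrix, one row per window, `2 * L` columns named
#'   `pos.<position>` then `neg.<position>`; all entries in (0, 1] when
#'   the pair was built with `alpha > 0`.
#' @export
bpb_encode <- function(windows, pair) {
  stopifnot(inherits(pair, "bpb_profile_pair"))
  windows <- as_window_matrix(windows, L = pair$L)
  out <- cbind(profile_lookup(windows, pair$positive),
               profile_lookup(windows, pair$negative))
  colnames(out) <- c(paste0("pos.", position_labels(pair$L)),
                     paste0("neg.", position_labels(pair$L)))
  rownames(out) <- rownames(windows)
  out
}

#' Naive-Bayes log-odds score
#'
#' The log posterior odds of the positive class under the
#' position-independence assumption:
#' `sum_i [log P(s_i|c1) - log P(s_i|c-1)]`, plus
#' `log P(c1) - log P(c-1)` when `use_priors` is TRUE. Natural
#' logarithms; only the sign and ordering of scores matter. The
#' normalising P(S) cancels in the odds and is never computed.
#'
#' @param windows window matrix (or records / sequences; coerced via
#'   [cterm_windows()] at the pair's L).
#' @param pair [profile_pair()] built with `alpha > 0`.
#' @param use_priors include the log prior odds term (default TRUE).
#' @return Numeric vector of log-odds scores, one per window.
#' @seealso [nb_classify()] for the sign decision rule.
#' @export
nb_score <- function(windows, pair, use_priors = TRUE) {
  stopifnot(inherits(pair, "bpb_profile_pair"))
  windows <- as_window_matrix(windows, L = pair$L)
  p1 <- profile_lookup(windows, pair$positive)
  p0 <- profile_lookup(windows, pair$negative)
  if (any(p1 == 0) || any(p0 == 0)) {
    stop("zero probability in profile; rebuild the pair with alpha > 0")
  }
  s <- rowSums(log(p1)) - rowSums(log(p0))
  if (use_priors) s <- s + (log(pair$priors[["pos"]]) - log(pair$priors[["neg"]]))
  unname(s)
}

#' Classify from a naive-Bayes log-odds score
#'
#' Sign decision rule: +1 for positive log-odds, -1 otherwise. An exact
#' tie (score 0) is called negative.
#'
#' @param score numeric vector of log-odds from [nb_score()].
#' @return Integer vector over \{+1, -1\}.
#' @export
nb_classify <- function(score) {
  ifelse(score > 0, 1L, -1L)
}

#' Export a position profile as a TSV matrix
#'
#' Positions as rows, residues as columns — the layout sequence-logo
#' tools consume.
#'
#' @param profile a [position_profile()] or the probability matrix of a
#'   [position_composition()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  prob <- if (inherits(profile, "position_profile")) profile$prob else profile
  df <- data.frame(position = rownames(prob), prob, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
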