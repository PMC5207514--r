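#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth integer vectors over \{+1, -1\}, aligned.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  c(TP = sum(predicted == 1L & truth == 1L),
    FP = sum(predicted == 1L & truth == -1L),
    TN = sum(predicted == -1L & truth == -1L),
    FN = sum(predicted == -1L & truth == 1L))
}

#' Binary classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#'
#' A zero denominator in sensitivity or specificity yields `NA` (not an
#' error); the MCC is reported as `NA` with `mcc_undefined = TRUE` when
#' any of its four marginal factors is zero, and prints as `N.A.`.
#'
#' @param counts named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return Object of class `pts1_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `mcc`, `mcc_undefined`, `counts`.
#' @examples
#' compute_metrics(c(TP = 75, FP = 2, TN = 174, FN = 15))
#' @export
compute_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "FP", "TN", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("need non-negative TP, FP, TN, FN")
  tp <- as.numeric(counts["TP"]); fp <- as.numeric(counts["FP"])
  tn <- as.numeric(counts["TN"]); fn <- as.numeric(counts["FN"])
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  undef <- any(fac == 0)
  mcc <- if (undef) NA_real_ else (tp * tn - fp * fn) / sqrt(prod(fac))
  structure(list(accuracy = (tp + tn) / total, sensitivity = sens,
                 specificity = spec, mcc = mcc, mcc_undefined = undef,
                 counts = counts),
            class = "pts1_metrics")
}

#' @export
print.pts1_metrics <- function(x, ...) {
  cat(sprintf("Acc = %s  Sens = %s  Spec = %s  MCC = %s  (TP=%d FP=%d TN=%d FN=%d)\n",
              format3(x$accuracy), format3(x$sensitivity),
              format3(x$specificity), format3(x$mcc),
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

#' Reconstruct integer confusion counts from printed rates
#'
#' Inverts rounded sensitivity/specificity back to integer counts given
#' the class sizes: `TP = round(sens * P)`, `TN = round(spec * N)`
#' (round half away from zero), `FN = P - TP`, `FP = N - TN`. Lets
#' published performance tables be checked against the metric formulas.
#'
#' @param sens,spec printed sensitivity and specificity in \[0, 1\].
#' @param P,N numbers of true positives and true negatives in the
#'   evaluation set.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @examples
#' reconstruct_confusion(0.833, 0.987, 90, 176)  # TP=75 FP=2 TN=174 FN=15
#' @export
reconstruct_confusion <- function(sens, spec, P, N) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1) {
    stop("sens and spec must lie in [0, 1]")
  }
  if (P < 1 || N < 1) stop("P and N must be positive")
  tp <- as.integer(round_half_away(sens * P))
  tn <- as.integer(round_half_away(spec * N))
  if (tp > P || tn > N) stop("rounded counts out of range")
  c(TP = tp, FP = as.integer(N) - tn, TN = tn, FN = as.integer(P) - tp)
}

# Stratified fold assignment: a random permutation of fold ids 1..k,
# balanced within the class.
make_folds <- function(n, k) {
  if (k > n) stop("k = ", k, " exceeds class size ", n)
  sample(rep_len(seq_len(k), n))
}

#' Stratified k-fold cross-validation of the bi-profile Bayes SVM
#'
#' Random stratified folds (deterministic given `seed`); within each
#' fold the class profiles and the SVM are refit on the training folds
#' only, and the held-out windows are scored. Held-out confusions are
#' pooled across folds before computing the headline metrics, so the
#' result is a single confusion over the whole dataset.
#'
#' @param pos,neg positive/negative training input: window matrices, or
#'   records/sequences (coerced with [cterm_windows()] at `L`).
#' @param k number of folds (default 5).
#' @param cutoff decision-value threshold for calling a positive
#'   (default 1.0, the model's conventional operating point).
#' @param L window length when `pos`/`neg` are not window matrices.
#' @param cost,gamma,kernel,alpha,class_weights passed to [pts1_svm()].
#' @param seed integer seed controlling fold assignment.
#' @return Object of class `pts1_cv`: list with `pooled`
#'   ([compute_metrics()] of the pooled confusion), `folds` (per-fold
#'   `pts1_metrics`), `scores` (data.frame id/truth/fold/score/label),
#'   `k`, `cutoff`, `seed`.
#' @export
cv_pts1_svm <- function(pos, neg, k = 5L, cutoff = 1, L = 30L,
                        cost = 1, gamma = NULL, kernel = "radial",
                        alpha = 1, class_weights = NULL, seed = 1L) {
  pw <- as_window_matrix(pos, L = L)
  nw <- as_window_matrix(neg, L = L)
  if (ncol(pw) != ncol(nw)) stop("class window lengths differ")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  set.seed(seed)
  fold_pos <- make_folds(nrow(pw), k)
  fold_neg <- make_folds(nrow(nw), k)

  score_all <- numeric(nrow(pw) + nrow(nw))
  fold_all <- c(fold_pos, fold_neg)
  truth <- rep(c(1L, -1L), c(nrow(pw), nrow(nw)))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    fit <- pts1_svm(pw[fold_pos != f, , drop = FALSE],
                    nw[fold_neg != f, , drop = FALSE],
                    kernel = kernel, cost = cost, gamma = gamma,
                    alpha = alpha, class_weights = class_weights)
    held <- rbind(pw[fold_pos == f, , drop = FALSE],
                  nw[fold_neg == f, , drop = FALSE])
    sc <- decision_score(fit, held)
    score_all[fold_all == f] <- sc
    folds[[f]] <- compute_metrics(confusion_counts(
      ifelse(sc >= cutoff, 1L, -1L), truth[fold_all == f]))
  }
  label <- ifelse(score_all >= cutoff, 1L, -1L)
  pooled <- compute_metrics(confusion_counts(label, truth))
  ids <- c(rownames(pw), rownames(nw))
  if (is.null(ids)) ids <- sprintf("w%d", seq_along(truth))
  structure(list(pooled = pooled, folds = folds,
                 scores = data.frame(id = ids, truth = truth,
                                     fold = fold_all, score = score_all,
                                     label = label,
                                     stringsAsFactors = FALSE),
                 k = k, cutoff = cutoff, seed = seed),
            class = "pts1_cv")
}

#' @export
print.pts1_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (cutoff %g, seed %d), pooled confusion:\n",
              x$k, x$cutoff, x$seed))
  print(x$pooled)
  invisible(x)
}

#' Metrics across a grid of decision cut-offs
#'
#' Re-thresholds a fixed set of decision scores at each cut-off
#' (`label = score >= cutoff`) and tabulates the four metrics, one row
#' per cut-off — the layout of a published cut-off comparison table.
#'
#' @param scores numeric decision values.
#' @param labels true labels over \{+1, -1\}, aligned with `scores`.
#' @param cutoffs numeric cut-offs; default is the conventional grid
#'   from -1.5 to 1.5 in steps of 0.5.
#' @return data.frame with columns `cutoff`, `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `accuracy`, `mcc` (`NA` where
#'   undefined).
#' @export
cutoff_sweep <- function(scores, labels,
                         cutoffs = seq(-1.5, 1.5, by = 0.5)) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (length(cutoffs) == 0L) stop("empty cutoff list")
  rows <- lapply(cutoffs, function(ct) {
    m <- compute_metrics(confusion_counts(ifelse(scores >= ct, 1L, -1L),
                                          labels))
    data.frame(cutoff = ct, TP = m$counts[["TP"]], FP = m$counts[["FP"]],
               TN = m$counts[["TN"]], FN = m$counts[["FN"]],
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, mcc = m$mcc)
  })
  do.call(rbind, rows)
}

#' Cross-validated performance across window lengths
#'
#' Runs the full CV pipeline once per candidate window length, to show
#' how much the sequence adjacent to the C-terminal tripeptide
#' contributes. Default lengths span the tripeptide alone up to 40
#' residues.
#'
#' @param pos_records,neg_records protein records or sequences (windows
#'   are re-extracted at each length).
#' @param lengths integer vector of window lengths.
#' @param ... passed to [cv_pts1_svm()] (`k`, `cutoff`, `cost`, `gamma`,
#'   `alpha`, `seed`, ...).
#' @return data.frame with one row per length: `L`, `TP`, `FP`, `TN`,
#'   `FN`, `sensitivity`, `specificity`, `accuracy`, `mcc`.
#' @export
length_sweep <- function(pos_records, neg_records,
                         lengths = c(3L, 5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L),
                         ...) {
  if (any(lengths < 1L)) stop("lengths must be >= 1")
  rows <- lapply(lengths, function(L) {
    m <- cv_pts1_svm(cterm_windows(pos_records, L),
                     cterm_windows(neg_records, L), ...)$pooled
    data.frame(L = L, TP = m$counts[["TP"]], FP = m$counts[["FP"]],
               TN = m$counts[["TN"]], FN = m$counts[["FN"]],
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, mcc = m$mcc)
  })
  do.call(rbind, rows)
}

#' Write a metrics table as TSV
#'
#' Numeric metric columns are printed at 3 decimals (half away from
#' zero); an undefined MCC prints as `N.A.`.
#'
#' @param table data.frame from [cutoff_sweep()] or [length_sweep()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(table, path) {
  out <- table
  for (col in intersect(c("sensitivity", "specificity", "accuracy", "mcc"),
                        names(out))) {
    out[[col]] <- format3(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
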