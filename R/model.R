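#' Fit the bi-profile Bayes SVM peroxisomal-protein classifier
#'
#' The core model: C-terminal windows from the two training classes are
#' encoded as bi-profile Bayes vectors (per-position residue
#' probabilities under the positive-class profile concatenated with
#' those under the negative-class profile) and a soft-margin SVM is
#' fitted on them. The fitted object is self-contained — it carries the
#' profile pair and window length it was trained with — so any future
#' query is encoded exactly as the training data were.
#'
#' @param pos,neg positive (peroxisomal) and negative training input:
#'   window matrices from [cterm_windows()], or records/sequences
#'   (coerced at `L`).
#' @param L window length used when coercing records (default 30; the
#'   last 30 residues carry the targeting signal and its adjacent
#'   context).
#' @param kernel `"radial"` (default; the kernel used for proteome
#'   scans), `"linear"` or `"polynomial"`.
#' @param cost soft-margin cost C (> 0).
#' @param gamma RBF/polynomial kernel width; default `1 / (2 * L)`, i.e.
#'   one over the feature dimension.
#' @param alpha pseudocount for the profile pair (default 1).
#' @param priors `"empirical"` or `"uniform"` class priors stored with
#'   the profile pair (used by the naive-Bayes score, not by the SVM).
#' @param class_weights optional named vector `c(pos = , neg = )` of SVM
#'   class weights; default unweighted despite the conventional 1:2
#'   class imbalance.
#' @param seed integer recorded in the model metadata. The fit itself is
#'   deterministic; the seed documents the training run.
#' @return Object of class `pts1_model`. Use [predict.pts1_model()] to
#'   score queries, [decision_score()] for raw SVM decision values,
#'   [save_pts1_model()] to persist.
#' @examples
#' set.seed(1)
#' d <- generate_synthetic(synthetic_spec(n_pos = 30, n_neg = 60, seed = 7))
#' fit <- pts1_svm(d$records[d$labels == 1, ], d$records[d$labels == -1, ])
#' fit
#' @export
pts1_svm <- function(pos, neg, L = 30L,
                     kernel = c("radial", "linear", "polynomial"),
                     cost = 1, gamma = NULL, alpha = 1,
                     priors = c("empirical", "uniform"),
                     class_weights = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  priors <- match.arg(priors)
  if (cost <= 0) stop("cost must be positive")
  pw <- as_window_matrix(pos, L = L)
  nw <- as_window_matrix(neg, L = L)
  if (nrow(pw) == 0L || nrow(nw) == 0L) {
    stop("both classes must be non-empty")
  }
  if (ncol(pw) != ncol(nw)) stop("class window lengths differ")
  L <- ncol(pw)
  if (is.null(gamma)) gamma <- 1 / (2 * L)
  if (gamma <= 0) stop("gamma must be positive")
  pair <- profile_pair(pw, nw, alpha = alpha, priors = priors)
  x <- rbind(bpb_encode(pw, pair), bpb_encode(nw, pair))
  y <- factor(rep(c("pos", "neg"), c(nrow(pw), nrow(nw))),
              levels = c("pos", "neg"))
  wts <- if (!is.null(class_weights)) class_weights else NULL
  fit <- e1071::svm(x, y, type = "C-classification", kernel = kernel,
                    cost = cost, gamma = gamma, class.weights = wts,
                    scale = FALSE)
  # libsvm orients decision values by class order of appearance; pin the
  # convention "positive class scores high" explicitly.
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1L]
  sign_flip <- if (mean(dv[y == "pos"]) >= mean(dv[y == "neg"])) 1 else -1
  structure(list(svm = fit, pair = pair, L = L, kernel = kernel,
                 cost = cost, gamma = gamma, alpha = alpha,
                 sign = sign_flip, seed = as.integer(seed),
                 n_pos = nrow(pw), n_neg = nrow(nw),
                 train_ids = c(rownames(pw), rownames(nw))),
            class = "pts1_model")
}

#' Raw SVM decision values for query windows
#'
#' Uncalibrated signed distances from the decision boundary, oriented so
#' that larger values mean more peroxisome-like. Typical magnitudes are
#' within roughly -3..3 but values are never clipped.
#'
#' @param model a fitted [pts1_svm()] model.
#' @param x windows, records or sequences; coerced at the model's `L`.
#' @return Numeric vector of decision values.
#' @export
decision_score <- function(model, x) {
  stopifnot(inherits(model, "pts1_model"))
  w <- as_window_matrix(x, L = model$L)
  if (ncol(w) != model$L) {
    stop("window length ", ncol(w), " does not match model L = ", model$L)
  }
  feats <- bpb_encode(w, model$pair)
  dv <- attr(stats::predict(model$svm, feats, decision.values = TRUE),
             "decision.values")[, 1L]
  unname(model$sign * dv)
}

#' Predict peroxisomal targeting for protein records
#'
#' Extracts the model-length C-terminal window of each query (short
#' queries are left-padded), computes its decision value, and calls a
#' positive when `score >= cutoff`.
#'
#' @param object a fitted [pts1_svm()] model.
#' @param newdata protein records (data.frame), sequences, or a window
#'   matrix.
#' @param cutoff decision threshold; 1.0 is the conventional default,
#'   1.5 the high-specificity setting used for whole-proteome scans.
#' @param ... unused.
#' @return data.frame with columns `id`, `score`, `label` (+1/-1 at the
#'   cutoff) and `cutoff`.
#' @export
predict.pts1_model <- function(object, newdata, cutoff = 1, ...) {
  if (missing(newdata)) stop("newdata is required")
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  w <- as_window_matrix(newdata, L = object$L)
  if (nrow(w) == 0L) stop("no query records")
  sc <- decision_score(object, w)
  ids <- rownames(w)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(sc))
  data.frame(id = ids, score = sc,
             label = ifelse(sc >= cutoff, 1L, -1L),
             cutoff = cutoff, stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.pts1_model <- function(x, ...) {
  cat("Bi-profile Bayes SVM for PTS1 peroxisomal targeting\n")
  cat(sprintf("  window length L = %d (positions %s..0), alpha = %g\n",
              x$L, position_labels(x$L)[1], x$alpha))
  cat(sprintf("  kernel = %s, cost = %g, gamma = %g\n",
              x$kernel, x$cost, x$gamma))
  cat(sprintf("  training: %d positive / %d negative windows, %d support vectors\n",
              x$n_pos, x$n_neg, nrow(x$svm$SV)))
  invisible(x)
}

#' Summarize a fitted model
#'
#' Extends the basic description with the range of the per-position
#' log-odds between the two class profiles and the window positions
#' where they disagree most — a quick view of where the learned signal
#' sits. For an honest performance estimate use [cv_pts1_svm()].
#'
#' @param object a `pts1_model`.
#' @param ... unused.
#' @method summary pts1_model
#' @export
summary.pts1_model <- function(object, ...) {
  lo <- log(object$pair$positive$prob) - log(object$pair$negative$prob)
  structure(list(model = object,
                 logodds_range = range(lo),
                 top_positions = utils::head(
                   rownames(lo)[order(-apply(abs(lo), 1, max))], 5L)),
            class = "summary.pts1_model")
}

#' @export
print.summary.pts1_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  per-position log-odds range: [%.2f, %.2f]\n",
              x$logodds_range[1], x$logodds_range[2]))
  cat("  most discriminative positions: ",
      paste(x$top_positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot the positional signal a fitted model has learned
#'
#' Bar chart of the total-variation distance between the positive and
#' negative class profiles at each window position — the positions where
#' the two training sets disagree most, with the targeting tripeptide at
#' positions -2..0 on the right.
#'
#' @param x a `pts1_model`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the per-position divergence vector.
#' @method plot pts1_model
#' @export
plot.pts1_model <- function(x, ...) {
  d <- composition_contrast(profile_composition(x$pair$positive),
                            profile_composition(x$pair$negative))
  graphics::barplot(d, names.arg = names(d), las = 2,
                    xlab = "position (0 = C-terminus)",
                    ylab = "total-variation distance",
                    main = "Positive vs negative positional divergence", ...)
  invisible(d)
}

#' Select SVM hyperparameters by stratified k-fold cross-validation
#'
#' Evaluates every (cost, gamma) cell on the same seeded stratified
#' folds; profiles and SVM are refit inside each training fold. The cell
#' maximizing pooled accuracy (labels at cutoff 0) wins; ties break to
#' the smaller cost, then the smaller gamma.
#'
#' @param pos,neg training windows (or records/sequences at `L`).
#' @param cost_grid,gamma_grid numeric grids; defaults are the usual
#'   powers of two, `2^(-5,-3,...,15)` and `2^(-15,-13,...,3)`.
#' @param k folds (default 5).
#' @param L,alpha,kernel,class_weights as in [pts1_svm()].
#' @param seed fold seed.
#' @return Object of class `pts1_tune`: list with `best_cost`,
#'   `best_gamma`, `table` (one row per cell with pooled metrics).
#' @export
tune_pts1_svm <- function(pos, neg,
                          cost_grid = 2^seq(-5, 15, by = 2),
                          gamma_grid = 2^seq(-15, 3, by = 2),
                          k = 5L, L = 30L, alpha = 1, kernel = "radial",
                          class_weights = NULL, seed = 1L) {
  if (length(cost_grid) == 0L || length(gamma_grid) == 0L) {
    stop("empty hyperparameter grid")
  }
  pw <- as_window_matrix(pos, L = L)
  nw <- as_window_matrix(neg, L = L)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cv <- cv_pts1_svm(pw, nw, k = k, cutoff = 0,
                      cost = grid$cost[i], gamma = grid$gamma[i],
                      kernel = kernel, alpha = alpha,
                      class_weights = class_weights, seed = seed)
    m <- cv$pooled
    data.frame(cost = grid$cost[i], gamma = grid$gamma[i],
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, mcc = m$mcc)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$accuracy, tab$cost, tab$gamma)
  best <- tab[ord[1L], ]
  structure(list(best_cost = best$cost, best_gamma = best$gamma,
                 table = tab, k = k, seed = seed),
            class = "pts1_tune")
}

#' @export
print.pts1_tune <- function(x, ...) {
  cat(sprintf("Grid search over %d cells (%d-fold CV): best cost = %g, gamma = %g, accuracy = %s\n",
              nrow(x$table), x$k, x$best_cost, x$best_gamma,
              format3(max(x$table$accuracy))))
  invisible(x)
}

MODEL_MAGIC <- "pts1pred_model"
MODEL_FORMAT_VERSION <- 1L

#' Save / load a fitted model
#'
#' The archive is versioned and self-contained (SVM state, profile
#' pair, window length, training metadata); a load followed by scoring
#' reproduces decision values bit-for-bit.
#'
#' @param model a `pts1_model`.
#' @param path file path for the model archive.
#' @return `save_pts1_model` returns `path` invisibly;
#'   `load_pts1_model` returns the restored `pts1_model`.
#' @export
save_pts1_model <- function(model, path) {
  stopifnot(inherits(model, "pts1_model"))
  saveRDS(list(magic = MODEL_MAGIC, version = MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname save_pts1_model
#' @export
load_pts1_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt model file: ", path)
  })
  if (!is.list(obj) || !identical(obj$magic, MODEL_MAGIC)) {
    stop("not a pts1pred model archive: ", path)
  }
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", obj$version)
  }
  obj$model
}

#' Write predictions as TSV
#'
#' One row per query — id, decision score (3 decimals), call, cutoff —
#' plus a trailing comment line with the call counts.
#'
#' @param predictions data.frame from [predict.pts1_model()].
#' @param path output TSV path.
#' @param model_id short string identifying the model used.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path, model_id = "pts1_svm") {
  out <- data.frame(id = predictions$id,
                    score = format3(predictions$score),
                    label = predictions$label,
                    cutoff = predictions$cutoff,
                    model = model_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  n_pos <- sum(predictions$label == 1L)
  cat(sprintf("# %d of %d queries called positive at cutoff %g\n",
              n_pos, nrow(predictions), predictions$cutoff[1L]),
      file = path, append = TRUE)
  invisible(path)
}
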