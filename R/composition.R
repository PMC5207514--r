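#' Per-position amino-acid composition of a window set
#'
#' Relative frequency of each of the 20 standard residues at each window
#' position — the numbers behind a sequence logo whose letter heights
#' are raw probabilities. Pad symbols (`'X'`) are excluded from each
#' position's denominator, so frequencies reflect observed residues
#' only; a position consisting solely of pads is flagged and returned as
#' `NA`.
#'
#' @param windows character window matrix ([cterm_windows()]).
#' @return Matrix of class `composition_matrix`, positions
#'   (rows, labelled `-(L-1)..0`) by the 20 standard residues; rows sum
#'   to 1 except flagged all-pad rows. Attribute `empty_positions`
#'   lists the flagged position labels.
#' @export
position_composition <- function(windows) {
  if (!is.matrix(windows) || nrow(windows) == 0L) {
    stop("'windows' must be a non-empty character matrix")
  }
  L <- ncol(windows)
  comp <- t(vapply(seq_len(L), function(j) {
    obs <- windows[, j][windows[, j] != "X"]
    if (length(obs) == 0L) return(rep(NA_real_, 20L))
    tabulate(match(obs, AA20), nbins = 20L) / length(obs)
  }, numeric(20L)))
  dimnames(comp) <- list(position_labels(L), AA20)
  empty <- rownames(comp)[is.na(comp[, 1L])]
  structure(comp, empty_positions = empty, class = "composition_matrix")
}

# Composition view of a smoothed position profile: drop the pad column
# and renormalise. At alpha = 0 this equals position_composition of the
# same windows (when no pads are present).
profile_composition <- function(profile) {
  p <- profile$prob[, AA20, drop = FALSE]
  p <- p / rowSums(p)
  structure(p, empty_positions = character(0), class = "composition_matrix")
}

#' Per-position divergence between two composition matrices
#'
#' Total-variation distance `0.5 * sum_a |p(a) - q(a)|` at each
#' position: 0 for identical compositions, 1 for disjoint residue
#' support. Used to locate the window positions where peroxisomal and
#' non-peroxisomal C-termini differ most.
#'
#' @param pos,neg `composition_matrix` objects of the same shape.
#' @return Named numeric vector of divergences in \[0, 1\], one per
#'   position label.
#' @export
composition_contrast <- function(pos, neg) {
  if (!all(dim(pos) == dim(neg))) stop("composition matrices differ in shape")
  d <- 0.5 * rowSums(abs(unclass(pos) - unclass(neg)))
  names(d) <- rownames(pos)
  d
}
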