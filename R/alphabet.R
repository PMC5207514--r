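# The 20 standard amino acids plus 'X', which doubles as the left-pad
# symbol for short proteins and as the catch-all for non-standard codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

# Average amino-acid frequencies in globular proteins (Robinson & Robinson
# style background); used by the synthetic generator's "natural" option.
AA_NATURAL <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)

#' Amino-acid alphabet used throughout the package
#'
#' @param include_x logical; include the pad/unknown symbol `'X'`.
#' @return Character vector of residue symbols.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function(include_x = TRUE) {
  if (include_x) AA21 else AA20
}

# Position labels for a window of length L: -(L-1), ..., -1, 0 with 0 at
# the C-terminus.
position_labels <- function(L) as.character(seq.int(-(L - 1L), 0L))

# Round half away from zero (what printed 3-decimal tables use).
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a metric at 3 decimals
#'
#' Rounds half away from zero — the convention of printed performance
#' tables — and renders `NA` (an undefined MCC) as `"N.A."`.
#'
#' @param x numeric vector.
#' @return Character vector.
#' @examples
#' format3(c(0.9365, NA))
#' @export
format3 <- function(x) {
  out <- sprintf("%.3f", round_half_away(x, 3L))
  out[is.na(x)] <- "N.A."
  out
}
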