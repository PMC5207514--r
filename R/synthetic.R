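#' Specification for the synthetic two-class sequence generator
#'
#' Describes the statistical structure the classifier assumes: positive
#' sequences end in a canonical PTS1-like tripeptide and carry enriched
#' residues at a handful of upstream positions; negative sequences have
#' unbiased composition and never end in a motif tripeptide. Defaults
#' mirror the curated Arabidopsis study set: 90 positives vs 176
#' negatives (about the conventional 1:2 ratio), a 30-residue window,
#' six canonical tripeptides, and upstream bias at positions
#' -22..-20, -14 and -6..-4.
#'
#' @param n_pos,n_neg class sizes (default 90 / 176).
#' @param L window length within which biased positions are defined.
#' @param motifs character vector of terminal tripeptides for the
#'   positive class.
#' @param biased_positions integer positions (negative, 0 = terminus)
#'   carrying composition bias in positives.
#' @param enriched_residues residues enriched at `biased_positions`
#'   (recycled / matched by order).
#' @param enrichment probability in (0, 1] that a biased position holds
#'   its enriched residue (default 0.5; the rest of the mass is spread
#'   over the background).
#' @param background `"uniform"` over the 20 standard residues (exactly
#'   known null, default) or `"natural"` average protein composition.
#' @param length_range integer range of full sequence lengths.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 90L, n_neg = 176L, L = 30L,
                           motifs = c("SKL", "ARL", "SRL", "SKM", "PKL", "SRM"),
                           biased_positions = c(-22L, -21L, -20L, -14L, -6L, -5L, -4L),
                           enriched_residues = c("P", "E", "S", "L", "A", "R", "H"),
                           enrichment = 0.5,
                           background = c("uniform", "natural"),
                           length_range = c(50L, 500L), seed = 1L) {
  background <- match.arg(background)
  if (n_pos < 1L || n_neg < 1L) stop("class sizes must be >= 1")
  if (enrichment <= 0 || enrichment > 1) stop("enrichment must be in (0, 1]")
  if (any(nchar(motifs) != 3L)) stop("motifs must be tripeptides")
  if (any(biased_positions > -1L | biased_positions < -(L - 1L))) {
    stop("biased positions must lie in -(L-1)..-1")
  }
  enriched_residues <- rep_len(enriched_residues, length(biased_positions))
  if (length_range[1L] < L) {
    stop("minimum sequence length must be >= L so bias positions exist")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 L = as.integer(L), motifs = toupper(motifs),
                 biased_positions = as.integer(biased_positions),
                 enriched_residues = toupper(enriched_residues),
                 enrichment = enrichment, background = background,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic two-class dataset
#'
#' Draws full-length background sequences, then: positives get a motif
#' tripeptide (uniform over the motif set) at the last three positions
#' and, with probability `enrichment`, their enriched residue at each
#' biased position; negatives are resampled at the terminal tripeptide
#' until it falls outside the motif set. Deterministic given the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param max_reject cap on resampling rounds for negative termini.
#' @return Object of class `pts1_dataset`: list with `records` (id,
#'   desc, seq data.frame), `labels` (+1/-1 aligned with records), and
#'   `provenance`.
#' @export
generate_synthetic <- function(spec, max_reject = 1000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bg <- if (spec$background == "uniform") {
    stats::setNames(rep(1 / 20, 20), AA20)
  } else {
    AA_NATURAL / sum(AA_NATURAL)
  }
  draw_seq <- function(n) {
    len <- sample(seq.int(spec$length_range[1L], spec$length_range[2L]),
                  n, replace = TRUE)
    vapply(len, function(l) {
      paste(sample(AA20, l, replace = TRUE, prob = bg), collapse = "")
    }, character(1))
  }
  set_terminal <- function(s, tri) {
    paste0(substr(s, 1L, nchar(s) - 3L), tri)
  }

  pos <- draw_seq(spec$n_pos)
  # upstream composition bias, applied per biased position
  for (i in seq_along(spec$biased_positions)) {
    off <- -spec$biased_positions[i]  # residues before the terminus
    hit <- stats::runif(spec$n_pos) < spec$enrichment
    idx <- which(hit)
    if (length(idx)) {
      at <- nchar(pos[idx]) - off
      substr(pos[idx], at, at) <- spec$enriched_residues[i]
    }
  }
  pos <- set_terminal(pos, sample(spec$motifs, spec$n_pos, replace = TRUE))

  neg <- draw_seq(spec$n_neg)
  tri <- substr(neg, nchar(neg) - 2L, nchar(neg))
  iter <- 0L
  while (any(tri %in% spec$motifs)) {
    iter <- iter + 1L
    if (iter > max_reject) stop("negative resampling cap exceeded; motif set too broad")
    redo <- which(tri %in% spec$motifs)
    fresh <- vapply(redo, function(i) {
      paste(sample(AA20, 3L, replace = TRUE, prob = bg), collapse = "")
    }, character(1))
    neg[redo] <- set_terminal(neg[redo], fresh)
    tri <- substr(neg, nchar(neg) - 2L, nchar(neg))
  }

  records <- data.frame(
    id = c(sprintf("pos_%03d", seq_len(spec$n_pos)),
           sprintf("neg_%03d", seq_len(spec$n_neg))),
    desc = rep(c("synthetic peroxisomal", "synthetic non-peroxisomal"),
               c(spec$n_pos, spec$n_neg)),
    seq = c(pos, neg), stringsAsFactors = FALSE)
  structure(list(records = records,
                 labels = rep(c(1L, -1L), c(spec$n_pos, spec$n_neg)),
                 provenance = sprintf(
                   "synthetic (seed %d, enrichment %g, background %s)",
                   spec$seed, spec$enrichment, spec$background)),
            class = "pts1_dataset")
}

#' @export
print.pts1_dataset <- function(x, ...) {
  cat(sprintf("Labelled dataset: %d positive / %d negative records (%s)\n",
              sum(x$labels == 1L), sum(x$labels == -1L), x$provenance))
  invisible(x)
}

#' Split a labelled dataset into positive and negative records
#'
#' @param dataset a `pts1_dataset`.
#' @return List with elements `pos` and `neg`, each a record data.frame.
#' @export
split_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "pts1_dataset"))
  list(pos = dataset$records[dataset$labels == 1L, , drop = FALSE],
       neg = dataset$records[dataset$labels == -1L, , drop = FALSE])
}

#' Greedy redundancy filter on C-terminal window identity
#'
#' A deliberately simple, reproducible stand-in for alignment-based
#' redundancy removal: records are visited in input order and kept only
#' if the fraction of matching window positions against every
#' already-kept record stays below `identity_threshold`.
#'
#' @param records protein records or sequences.
#' @param identity_threshold identity fraction in (0, 1\] at or above
#'   which a record is considered redundant (default 0.9).
#' @param L window length over which identity is computed.
#' @return The kept records, same format as the input data.frame.
#' @export
redundancy_filter <- function(records, identity_threshold = 0.9, L = 30L) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  records <- as_protein_records(records)
  w <- cterm_windows(records, L = L)
  keep <- integer(0)
  for (i in seq_len(nrow(w))) {
    redundant <- FALSE
    for (j in keep) {
      if (mean(w[i, ] == w[j, ]) >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, i)
  }
  records[keep, , drop = FALSE]
}

#' Assemble a labelled dataset from positive and negative records
#'
#' @param pos_records,neg_records record data.frames (ids must not
#'   collide across classes).
#' @param provenance free-text note stored with the dataset.
#' @return A `pts1_dataset` with labels +1 then -1, input order kept.
#' @export
assemble_dataset <- function(pos_records, neg_records,
                             provenance = "assembled") {
  pos_records <- as_protein_records(pos_records)
  neg_records <- as_protein_records(neg_records)
  if (nrow(pos_records) == 0L || nrow(neg_records) == 0L) {
    stop("both classes must be non-empty")
  }
  clash <- intersect(pos_records$id, neg_records$id)
  if (length(clash)) {
    stop("record ids appear in both classes: ", paste(clash, collapse = ", "))
  }
  structure(list(records = rbind(pos_records, neg_records),
                 labels = rep(c(1L, -1L),
                              c(nrow(pos_records), nrow(neg_records))),
                 provenance = provenance),
            class = "pts1_dataset")
}

#' Write a labelled dataset as paired FASTA files
#'
#' @param dataset a `pts1_dataset`.
#' @param dir output directory (created if needed); files are
#'   `positive.fa` and `negative.fa`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_dataset_fasta <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pts1_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- split_dataset(dataset)
  paths <- c(positive = file.path(dir, "positive.fa"),
             negative = file.path(dir, "negative.fa"))
  write_fasta(parts$pos, paths[["positive"]])
  write_fasta(parts$neg, paths[["negative"]])
  invisible(paths)
}
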