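#' Clean a raw protein sequence
#'
#' Uppercases the sequence, strips whitespace, removes a single trailing
#' stop symbol (`'*'`), and maps every remaining non-standard symbol
#' (B, Z, J, U, O, gaps, internal stops, ...) to `'X'`.
#'
#' @param raw character vector of raw sequences.
#' @return Character vector of cleaned sequences over the 21-letter
#'   alphabet (see [aa_alphabet()]).
#' @examples
#' clean_sequence("mSkL")    # "MSKL"
#' clean_sequence("MS-KL*")  # "MSXKL"
#' @export
clean_sequence <- function(raw) {
  if (length(raw) == 0L) stop("no sequences supplied")
  x <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  x <- sub("\\*$", "", x)                       # one trailing stop only
  x <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", x)  # everything else -> X
  if (any(!nzchar(x))) {
    stop("sequence empty after cleaning: ",
         paste(which(!nzchar(x)), collapse = ", "))
  }
  x
}

#' Read protein records from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file and returns
#' one cleaned record per entry, in file order. The first whitespace-
#' delimited token of each header is the record id; the remainder is kept
#' as the description. Duplicate ids are deduplicated with a numeric
#' suffix, with a warning.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `id`, `desc`, `seq` (cleaned
#'   residues).
#' @seealso [write_fasta()], [clean_sequence()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    warning("duplicate FASTA ids deduplicated: ", paste(dup, collapse = ", "))
    id <- make.unique(id, sep = "_")
  }
  data.frame(id = id, desc = desc,
             seq = clean_sequence(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records to a FASTA file
#'
#' @param records data.frame with columns `id`, `seq` and optionally
#'   `desc`, as returned by [read_fasta()].
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_protein_records(records)
  header <- ifelse(nzchar(records$desc),
                   paste(records$id, records$desc), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- header
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Coerce common inputs (data.frame of records, named/unnamed character
# vector of sequences) to the canonical record data.frame.
as_protein_records <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      stop("record data.frame needs columns 'id' and 'seq'")
    }
    if (is.null(x$desc)) x$desc <- ""
    return(x[, c("id", "desc", "seq")])
  }
  if (is.character(x)) {
    id <- names(x)
    if (is.null(id)) id <- sprintf("seq_%d", seq_along(x))
    return(data.frame(id = id, desc = "", seq = unname(x),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret input of class ", paste(class(x), collapse = "/"),
       " as protein records")
}

#' Extract fixed-length C-terminal windows
#'
#' Takes the last `L` residues of each sequence. Sequences shorter than
#' `L` are kept and left-padded with `'X'`, so the C-terminal residue
#' always sits at position 0. Positions are labelled
#' `-(L-1), ..., -1, 0`, 0 being the terminus.
#'
#' @param x protein records (data.frame from [read_fasta()]) or a
#'   character vector of cleaned sequences.
#' @param L window length in residues (default 30).
#' @return Character matrix, one row per sequence, `L` columns named by
#'   position label; rownames are record ids.
#' @examples
#' cterm_windows(c("MASKL", "KL"), L = 4)
#' @export
cterm_windows <- function(x, L = 30L) {
  records <- as_protein_records(x)
  L <- as.integer(L)
  if (L < 1L) stop("window length L must be >= 1")
  n <- nrow(records)
  len <- nchar(records$seq)
  suffix <- substr(records$seq, pmax(1L, len - L + 1L), len)
  pad <- strrep("X", pmax(0L, L - len))
  padded <- paste0(pad, suffix)
  m <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
              nrow = n, ncol = L, byrow = TRUE)
  dimnames(m) <- list(records$id, position_labels(L))
  m
}

# Validate a window matrix and return it; used by downstream entry points.
as_window_matrix <- function(x, L = 30L) {
  if (is.matrix(x) && is.character(x)) {
    if (is.null(colnames(x))) colnames(x) <- position_labels(ncol(x))
    return(x)
  }
  cterm_windows(x, L = L)
}
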