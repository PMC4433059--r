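#' Amino-acid alphabet used throughout
#'
#' The 20 standard residues in alphabetical one-letter order. Profile score
#' matrices are indexed by this order; 'X' (unknown residue) is handled
#' separately and never appears in the alphabet.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' The eight Rid subfamilies in canonical order
#'
#' RidA first, then Rid1..Rid7. This order is also the deterministic
#' tie-break order used by [assign_subfamily()].
#'
#' @return Character vector of length 8.
#' @export
rid_subfamilies <- function() {
  c("RidA", paste0("Rid", 1:7))
}

#' Construct a multiple protein alignment object
#'
#' A minimal container for an aligned block of protein sequences: all rows
#' must have the same length and use the 20-letter amino-acid alphabet plus
#' the gap symbol '-' (and 'X' for unknown residues).
#'
#' @param id Alignment identifier.
#' @param seqs Named character vector of aligned sequences (names are
#'   sequence ids). Lower case is normalized to upper case.
#' @return An object of class `rid_alignment` with elements `id`, `seq_ids`,
#'   `seqs` and `n_columns`.
#' @export
new_alignment <- function(id, seqs) {
  if (length(seqs) < 2L) {
    stop("alignment '", id, "' must have at least 2 rows")
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("alignment rows must be named with sequence ids")
  }
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment '", id, "' rows differ in length: ",
         paste(unique(widths), collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "X-]"), seqs)
  if (any(bad)) {
    stop("alignment '", id, "' contains non-amino-acid characters in rows: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  structure(
    list(id = id, seq_ids = names(seqs), seqs = unname(seqs),
         n_columns = widths[[1L]]),
    class = "rid_alignment"
  )
}

#' @export
print.rid_alignment <- function(x, ...) {
  cat("rid_alignment '", x$id, "': ", length(x$seqs), " rows x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file into an alignment
#'
#' @param path Path to an aligned FASTA file ('-' as gap).
#' @param id Alignment id; defaults to the file name without extension.
#' @return A `rid_alignment`.
#' @export
read_alignment <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  recs <- read_fasta(path, alphabet = "align")
  new_alignment(id, recs)
}

# alignment as a character matrix (rows x columns)
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "rid_alignment"))
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}
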