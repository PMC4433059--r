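#' Read a protein FASTA file
#'
#' Sequences are normalized to upper case. Duplicate ids and empty files are
#' rejected rather than coerced.
#'
#' @param path Path to a FASTA file.
#' @param alphabet "protein" (default; 20 residues plus X allowed) or
#'   "align" (additionally allows the gap symbol '-').
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("protein", "align")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty input: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty input: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  allowed <- paste(aa_alphabet(), collapse = "")
  pat <- if (alphabet == "align") paste0("[^", allowed, "X-]")
         else paste0("[^", allowed, "X]")
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    stop("non-amino-acid characters in records: ",
         paste(ids[bad], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write protein sequences as FASTA
#'
#' Wraps sequence lines at 60 columns; upper-case output. Round-trips with
#' [read_fasta()] on ids and sequences.
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) stop("refusing to write empty record set")
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("all records must be named")
  }
  dup <- unique(names(records)[duplicated(names(records))])
  if (length(dup)) stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  set <- Biostrings::BStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read gene features (GFF3 subset or 7-column TSV)
#'
#' The GFF3 dialect is the `type=gene` subset with attributes `ID=`,
#' `genome_id=` and `role=`; the TSV dialect has the seven columns
#' genome_id, contig, gene_id, start, end, strand, role (with header).
#' Coordinates are 1-based inclusive. Unknown or missing roles map to OTHER
#' with one warning; malformed records (end < start, missing strand) are
#' rejected with their line number.
#'
#' @param path Input path.
#' @param dialect "gff3" or "tsv".
#' @return Data frame with columns genome_id, contig, gene_id, start, end,
#'   strand, role.
#' @export
read_features <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "tsv") {
    keep <- which(!grepl("^#", lines) & nzchar(lines))
    if (length(keep) == 0L) stop("empty input: ", path)
    header <- strsplit(lines[[keep[1L]]], "\t", fixed = TRUE)[[1L]]
    want <- c("genome_id", "contig", "gene_id", "start", "end", "strand", "role")
    if (!identical(header, want)) {
      stop("TSV header must be: ", paste(want, collapse = ", "))
    }
    body <- keep[-1L]
    if (length(body) == 0L) stop("no feature rows in ", path)
    parts <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 7L)) {
      stop("line(s) ", paste(body[nf != 7L], collapse = ", "),
           ": expected 7 tab-separated fields")
    }
    m <- do.call(rbind, parts)
    df <- data.frame(genome_id = m[, 1L], contig = m[, 2L], gene_id = m[, 3L],
                     start = suppressWarnings(as.integer(m[, 4L])),
                     end = suppressWarnings(as.integer(m[, 5L])),
                     strand = m[, 6L], role = m[, 7L])
    validate_feature_rows(df, body)
    return(normalize_roles(df))
  }
  # gff3 subset
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(keep) == 0L) stop("empty input: ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    stop("line(s) ", paste(keep[nf != 9L], collapse = ", "),
         ": expected 9 tab-separated GFF3 fields")
  }
  m <- do.call(rbind, parts)
  is_gene <- m[, 3L] == "gene"
  m <- m[is_gene, , drop = FALSE]
  keep <- keep[is_gene]
  if (nrow(m) == 0L) stop("no type=gene records in ", path)
  attr_get <- function(attrs, key) {
    hits <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(hits, function(g) if (length(g) >= 2L) g[[2L]] else NA_character_,
           character(1))
  }
  ids <- attr_get(m[, 9L], "ID")
  if (anyNA(ids)) {
    stop("line(s) ", paste(keep[is.na(ids)], collapse = ", "),
         ": missing ID attribute")
  }
  genome <- attr_get(m[, 9L], "genome_id")
  genome[is.na(genome)] <- m[is.na(genome), 1L]  # fall back to seqid
  role <- attr_get(m[, 9L], "role")
  df <- data.frame(genome_id = genome, contig = m[, 1L], gene_id = ids,
                   start = suppressWarnings(as.integer(m[, 4L])),
                   end = suppressWarnings(as.integer(m[, 5L])),
                   strand = m[, 7L], role = role)
  validate_feature_rows(df, keep)
  normalize_roles(df)
}

validate_feature_rows <- function(df, line_numbers) {
  bad_coord <- is.na(df$start) | is.na(df$end) | df$start < 1L |
    df$end < df$start
  if (any(bad_coord)) {
    stop("line(s) ", paste(line_numbers[bad_coord], collapse = ", "),
         ": malformed coordinates (need 1 <= start <= end), gene_id(s) ",
         paste(df$gene_id[bad_coord], collapse = ", "))
  }
  bad_strand <- !(df$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("line(s) ", paste(line_numbers[bad_strand], collapse = ", "),
         ": missing or invalid strand")
  }
  invisible(df)
}

#' Controlled vocabulary of partner-gene roles
#'
#' Roles for the PLP-enzyme and carbamoyl-phosphate-related partner genes
#' whose chromosomal clustering with Rid genes is scored, plus the
#' RID:<subfamily> labels and OTHER.
#'
#' @return Character vector of known role labels.
#' @export
known_roles <- function() {
  c("THREONINE_DEHYDRATASE", "ASPARTATE_AMINOTRANSFERASE",
    "CYSTEINE_DESULFURASE", "CYSTATHIONINE_BETA_LYASE", "TRYPTOPHANASE",
    "AMINE_OXIDASE", "ACT", "OCT", "CPS", "CK",
    paste0("RID:", rid_subfamilies()), "OTHER")
}

normalize_roles <- function(df) {
  unknown <- is.na(df$role) | !(df$role %in% known_roles())
  if (any(unknown)) {
    warning(sum(unknown), " feature(s) with missing/unknown role mapped to OTHER")
    df$role[unknown] <- "OTHER"
  }
  df
}

#' Write gene features (GFF3 subset or 7-column TSV)
#'
#' @param features Feature data frame as returned by [read_features()].
#' @param path Output path.
#' @param dialect "gff3" or "tsv".
#' @export
write_features <- function(features, path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (nrow(features) == 0L) stop("refusing to write empty feature set")
  if (dialect == "tsv") {
    write_tsv_strict(features[, c("genome_id", "contig", "gene_id", "start",
                                  "end", "strand", "role")], path)
    return(invisible(path))
  }
  lines <- c("##gff-version 3",
             sprintf("%s\tridscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s;genome_id=%s;role=%s",
                     features$contig, features$start, features$end,
                     features$strand, features$gene_id, features$genome_id,
                     features$role))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# Tab-separated writer with the fixed dialect used for all exports:
# tab separators, '#' comments, LF endings, no quoting, header row.
write_tsv_strict <- function(df, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con, sep = "\n")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

read_tsv_strict <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "", check.names = FALSE)
}
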