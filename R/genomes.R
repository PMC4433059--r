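#' Single-linkage MOTU clustering of a genome set
#'
#' Genomes are grouped into molecular operational taxonomic units (MOTUs)
#' by single-linkage agglomeration at a distance cutoff: the groups are the
#' connected components of the graph whose edges join genomes with
#' d(i, j) <= cutoff.
#'
#' @param distances Symmetric numeric matrix in [0, 1] with zero diagonal
#'   and genome ids as dimnames.
#' @param cutoff Distance threshold in (0, 1) (default 0.03).
#' @return List of groups, each `list(members, cutoff)`; groups partition
#'   the input and are ordered by their lexicographically smallest member.
#' @export
motu_cluster <- function(distances, cutoff = 0.03) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    stop("distances must be a square matrix")
  }
  if (is.null(rownames(distances))) {
    rownames(distances) <- colnames(distances) <- paste0("g", seq_len(nrow(distances)))
  }
  if (max(abs(distances - t(distances))) > 1e-9) {
    stop("distance matrix is asymmetric beyond 1e-9")
  }
  if (any(abs(diag(distances)) > 1e-12)) stop("diagonal must be zero")
  if (any(distances < 0 | distances > 1)) stop("distances must lie in [0, 1]")
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie in (0, 1)")
  adj <- (distances <= cutoff)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ids <- rownames(distances)
  groups <- split(ids, comp)
  groups <- lapply(groups, function(m) list(members = sort(m), cutoff = cutoff))
  groups <- groups[order(vapply(groups, function(g) g$members[[1L]], character(1)))]
  unname(groups)
}

#' Select the representative genome of a MOTU
#'
#' The member with the highest interest score (a proxy for the amount of
#' published data / research interest); exact ties are broken by the
#' lexicographically smallest genome id.
#'
#' @param group A group from [motu_cluster()] (`list(members, ...)`).
#' @param records Data frame with columns genome_id and interest_score.
#' @return The representative genome id.
#' @export
select_representative <- function(group, records) {
  members <- group$members
  missing <- setdiff(members, records$genome_id)
  if (length(missing)) {
    stop("missing genome record(s): ", paste(missing, collapse = ", "))
  }
  sc <- records$interest_score[match(members, records$genome_id)]
  members <- sort(members)                 # permutation invariance
  sc <- records$interest_score[match(members, records$genome_id)]
  members[which.max(sc)]                   # first max = smallest id on ties
}

#' Dereplicate a genome set into MOTU representatives
#'
#' @param distances Pairwise distance matrix (see [motu_cluster()]).
#' @param records Genome records with interest scores.
#' @param cutoff Single-linkage cutoff (default 0.03).
#' @return Data frame: motu (integer), representative, n_members, members
#'   (comma-joined).
#' @export
motu_dereplicate <- function(distances, records, cutoff = 0.03) {
  groups <- motu_cluster(distances, cutoff)
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(motu = i,
               representative = select_representative(g, records),
               n_members = length(g$members),
               members = paste(g$members, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-genome subfamily copy-number table
#'
#' Counts classified Rid proteins per (genome, subfamily); UNCLASSIFIED
#' rows are excluded and genomes without Rid genes appear with all-zero
#' rows. A fusion protein counts once by default ("gene copies"); set
#' `count_mode = "domains"` to weight by fusion domain count.
#'
#' @param classifications Classification table from [classify_proteome()].
#' @param records Genome records (genome_id, size_bp, optionally
#'   taxon_domain).
#' @param count_mode "proteins" (default) or "domains".
#' @return Data frame: genome_id, RidA..Rid7, total, size_bp (plus
#'   taxon_domain when present in `records`).
#' @export
copy_number_table <- function(classifications, records,
                              count_mode = c("proteins", "domains")) {
  count_mode <- match.arg(count_mode)
  cls <- classifications[classifications$subfamily %in% rid_subfamilies(), ,
                         drop = FALSE]
  stray <- setdiff(unique(cls$genome_id), records$genome_id)
  if (length(stray)) {
    stop("classification(s) reference unknown genome(s): ",
         paste(stray, collapse = ", "))
  }
  fams <- rid_subfamilies()
  ids <- sort(unique(records$genome_id))
  counts <- matrix(0L, nrow = length(ids), ncol = length(fams),
                   dimnames = list(ids, fams))
  if (nrow(cls) > 0L) {
    w <- if (count_mode == "domains") pmax(cls$fusion_count, 1L) else rep(1L, nrow(cls))
    for (i in seq_len(nrow(cls))) {
      counts[cls$genome_id[i], cls$subfamily[i]] <-
        counts[cls$genome_id[i], cls$subfamily[i]] + w[i]
    }
  }
  out <- data.frame(genome_id = ids, counts, check.names = FALSE)
  out$total <- rowSums(counts)
  out$size_bp <- records$size_bp[match(ids, records$genome_id)]
  if ("taxon_domain" %in% names(records)) {
    out$taxon_domain <- records$taxon_domain[match(ids, records$genome_id)]
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between genome size and Rid copy number
#'
#' @param table Distribution table from [copy_number_table()].
#' @param exclude_eukaryotes Drop eukaryote rows when a taxon_domain column
#'   is present (default TRUE, matching the convention of excluding
#'   eukaryote genome sizes from the comparison).
#' @return List with `r` (Pearson product-moment correlation) and `n`;
#'   `r` is NA with a `reason` attribute for degenerate inputs.
#' @export
size_correlation <- function(table, exclude_eukaryotes = TRUE) {
  tab <- table
  if (exclude_eukaryotes && "taxon_domain" %in% names(tab)) {
    tab <- tab[tab$taxon_domain != "eukaryote", , drop = FALSE]
  }
  if (nrow(tab) < 3L) {
    return(list(r = structure(NA_real_, reason = "fewer than 3 genomes"),
                n = nrow(tab)))
  }
  if (stats::sd(tab$size_bp) == 0 || stats::sd(tab$total) == 0) {
    return(list(r = structure(NA_real_, reason = "constant variable"),
                n = nrow(tab)))
  }
  list(r = stats::cor(tab$size_bp, tab$total, method = "pearson"),
       n = nrow(tab))
}

#' Export the distribution table as an iTOL-style multi-bar annotation
#'
#' One tab-delimited data line per tree leaf present in the table: leaf id,
#' the eight subfamily counts, then the genome size field. Row order
#' follows the tree's leaf order; table ids absent from the tree are
#' reported, never silently dropped.
#'
#' @param table Distribution table from [copy_number_table()].
#' @param tree Newick text (or a path via [ape::read.tree] upstream).
#' @return List: `lines` (character vector: header comment + data lines),
#'   `unmatched` (table genome ids absent from the tree).
#' @export
export_itol <- function(table, tree) {
  phy <- tryCatch(ape::read.tree(text = tree),
                  error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed newick: parser returned NULL")
  leaves <- phy$tip.label
  unmatched <- setdiff(table$genome_id, leaves)
  fams <- rid_subfamilies()
  keep <- table[match(leaves, table$genome_id), , drop = FALSE]
  keep <- keep[!is.na(keep$genome_id), , drop = FALSE]
  header <- paste(c("#leaf", fams, "size_bp"), collapse = "\t")
  data_lines <- vapply(seq_len(nrow(keep)), function(i) {
    paste(c(keep$genome_id[i], as.integer(keep[i, fams]), keep$size_bp[i]),
          collapse = "\t")
  }, character(1))
  list(lines = c(header, data_lines), unmatched = unmatched)
}

#' Write an iTOL export to disk
#'
#' @param export Result of [export_itol()].
#' @param path Output path.
#' @export
write_itol <- function(export, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(export$lines, con, sep = "\n")
  invisible(path)
}

#' Parse an iTOL export back into a count table (round-trip check)
#'
#' @param lines Character vector as produced by [export_itol()].
#' @return Data frame: genome_id, RidA..Rid7, size_bp.
#' @export
parse_itol <- function(lines) {
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  m <- do.call(rbind, parts)
  fams <- rid_subfamilies()
  out <- data.frame(genome_id = m[, 1L],
                    matrix(as.integer(m[, 2:9]), ncol = 8L,
                           dimnames = list(NULL, fams)),
                    size_bp = as.numeric(m[, 10L]), check.names = FALSE)
  out
}
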