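#' Find Rid-gene / partner-gene chromosomal clustering events
#'
#' A clustering event is a (Rid gene, partner-role gene) pair on the same
#' contig separated by at most `max_intervening` genes in genomic order and
#' a nearest-boundary gap of at most `max_gap_bp`, subject to the strand
#' policy. One event per pair: a Rid gene near two partner genes yields two
#' events. Defaults (3 intervening genes, 5 kb) follow typical
#' operon-context heuristics.
#'
#' @param features Feature data frame (genome_id, contig, gene_id, start,
#'   end, strand, role); sorted defensively per contig.
#' @param rid_genes Data frame (gene_id, subfamily) identifying classified
#'   Rid genes; defaults to features whose role is "RID:<subfamily>".
#' @param partner_roles Character vector of partner roles to score;
#'   defaults to all non-RID, non-OTHER roles present.
#' @param max_intervening Maximum genes between the pair (default 3).
#' @param max_gap_bp Maximum nearest-boundary gap in bp (default 5000).
#' @param strand_policy "any" (default), "same", or "divergent_ok" (same
#'   strand or divergent orientation; convergent pairs excluded).
#' @return Data frame of events: genome_id, contig, rid_gene_id,
#'   rid_subfamily, partner_gene_id, partner_role, intervening_genes,
#'   gap_bp, same_strand.
#' @export
find_cluster_events <- function(features, rid_genes = NULL,
                                partner_roles = NULL,
                                max_intervening = 3L, max_gap_bp = 5000L,
                                strand_policy = c("any", "same", "divergent_ok")) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(max_intervening >= 0L, max_gap_bp >= 0L)
  bad <- is.na(features$start) | is.na(features$end) |
    features$start < 1L | features$end < features$start
  if (any(bad)) {
    stop("malformed coordinates for gene_id(s): ",
         paste(features$gene_id[bad], collapse = ", "))
  }
  if (is.null(rid_genes)) {
    is_rid <- startsWith(features$role, "RID:")
    rid_genes <- data.frame(gene_id = features$gene_id[is_rid],
                            subfamily = sub("^RID:", "", features$role[is_rid]))
  }
  unknown <- !(rid_genes$subfamily %in% rid_subfamilies())
  if (any(unknown)) {
    warning("skipping rid gene(s) with unknown subfamily: ",
            paste(rid_genes$gene_id[unknown], collapse = ", "))
    rid_genes <- rid_genes[!unknown, , drop = FALSE]
  }
  if (is.null(partner_roles)) {
    partner_roles <- setdiff(unique(features$role),
                             c("OTHER", paste0("RID:", rid_subfamilies())))
  }
  empty <- data.frame(genome_id = character(0), contig = character(0),
                      rid_gene_id = character(0), rid_subfamily = character(0),
                      partner_gene_id = character(0), partner_role = character(0),
                      intervening_genes = integer(0), gap_bp = integer(0),
                      same_strand = logical(0))
  if (nrow(rid_genes) == 0L) return(empty)

  out <- list()
  for (key in unique(paste(features$genome_id, features$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    ctg <- features[features$genome_id == parts[[1L]] &
                      features$contig == parts[[2L]], , drop = FALSE]
    ctg <- ctg[order(ctg$start, ctg$end, ctg$gene_id), , drop = FALSE]
    ctg$rank <- seq_len(nrow(ctg))
    rid_idx <- which(ctg$gene_id %in% rid_genes$gene_id)
    par_idx <- which(ctg$role %in% partner_roles)
    if (length(rid_idx) == 0L || length(par_idx) == 0L) next
    for (ri in rid_idx) {
      for (pi in par_idx) {
        if (ri == pi) next
        intervening <- abs(ctg$rank[ri] - ctg$rank[pi]) - 1L
        if (intervening > max_intervening) next
        gap <- max(0L, max(ctg$start[ri], ctg$start[pi]) -
                     min(ctg$end[ri], ctg$end[pi]) - 1L)
        if (gap > max_gap_bp) next
        same <- ctg$strand[ri] == ctg$strand[pi]
        if (strand_policy == "same" && !same) next
        if (strand_policy == "divergent_ok" && !same) {
          # exclude convergent pairs (-> <-): upstream gene on '+',
          # downstream on '-'
          up <- if (ctg$start[ri] <= ctg$start[pi]) ri else pi
          dn <- if (up == ri) pi else ri
          if (ctg$strand[up] == "+" && ctg$strand[dn] == "-") next
        }
        out[[length(out) + 1L]] <- data.frame(
          genome_id = parts[[1L]], contig = parts[[2L]],
          rid_gene_id = ctg$gene_id[ri],
          rid_subfamily = rid_genes$subfamily[match(ctg$gene_id[ri],
                                                    rid_genes$gene_id)],
          partner_gene_id = ctg$gene_id[pi],
          partner_role = ctg$role[pi],
          intervening_genes = intervening, gap_bp = gap, same_strand = same)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$genome_id, res$contig, res$rid_gene_id,
                   res$partner_gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-role subfamily clustering frequencies (pie statistics)
#'
#' For each partner role, the relative frequency with which clustering
#' occurs with each Rid subfamily: instances(subfamily) / instances(all).
#' Roles with zero events are omitted.
#'
#' @param events Event data frame from [find_cluster_events()].
#' @return Long data frame: role, subfamily, count, frequency (per-role
#'   frequencies sum to 1).
#' @export
subfamily_frequencies <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(role = character(0), subfamily = character(0),
                      count = integer(0), frequency = numeric(0)))
  }
  tab <- as.data.frame(table(role = events$partner_role,
                             subfamily = events$rid_subfamily),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  tab <- tab[tab$count > 0L, , drop = FALSE]
  totals <- tapply(tab$count, tab$role, sum)
  tab$frequency <- tab$count / as.numeric(totals[tab$role])
  tab <- tab[order(tab$role, match(tab$subfamily, rid_subfamilies())), ]
  rownames(tab) <- NULL
  tab
}

#' Per-role genome proportions and instance counts (bar statistics)
#'
#' For each role, the proportion of genomes (out of the supplied genome
#' set) with at least one clustering event, plus the total number of event
#' instances. Both are reported because figure legends describe proportions
#' while captions cite instance counts.
#'
#' @param events Event data frame from [find_cluster_events()].
#' @param genomes Character vector of genome ids defining the denominator.
#' @param roles Roles to report; defaults to those present in `events`.
#' @return Data frame: role, genomes_with_event, proportion, instance_count.
#' @export
role_genome_proportions <- function(events, genomes, roles = NULL) {
  if (length(genomes) == 0L) stop("genome set must be non-empty")
  stray <- setdiff(unique(events$genome_id), genomes)
  if (length(stray)) {
    stop("event(s) reference genome(s) outside the set: ",
         paste(stray, collapse = ", "))
  }
  if (is.null(roles)) roles <- sort(unique(events$partner_role))
  rows <- lapply(roles, function(r) {
    ev <- events[events$partner_role == r, , drop = FALSE]
    data.frame(role = r,
               genomes_with_event = length(unique(ev$genome_id)),
               proportion = length(unique(ev$genome_id)) / length(genomes),
               instance_count = nrow(ev))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(role = character(0), genomes_with_event = integer(0),
                      proportion = numeric(0), instance_count = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Fraction of focal-subfamily clusters that also contain a companion
#'
#' Among clustering events whose Rid gene belongs to `focal`, the fraction
#' for which a `companion`-subfamily gene lies within `max_intervening`
#' genes of either the focal Rid gene or its partner gene on the same
#' contig (e.g. the share of Rid7 clusters that also contain RidA).
#'
#' @param events Event data frame from [find_cluster_events()].
#' @param features Full feature data frame (to locate companion genes).
#' @param focal,companion Distinct subfamily labels.
#' @param max_intervening Maximum genes between companion and anchor
#'   (default 3).
#' @return Fraction in [0, 1]; NA (with a "reason" attribute) when there
#'   are no focal events.
#' @export
co_cluster_fraction <- function(events, features, focal, companion,
                                max_intervening = 3L) {
  if (identical(focal, companion)) stop("focal and companion must differ")
  ev <- events[events$rid_subfamily == focal, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(structure(NA_real_, reason = "no focal events"))
  }
  comp_role <- paste0("RID:", companion)
  hit <- vapply(seq_len(nrow(ev)), function(i) {
    ctg <- features[features$genome_id == ev$genome_id[i] &
                      features$contig == ev$contig[i], , drop = FALSE]
    ctg <- ctg[order(ctg$start, ctg$end, ctg$gene_id), , drop = FALSE]
    ranks <- seq_len(nrow(ctg))
    comp <- which(ctg$role == comp_role)
    if (length(comp) == 0L) return(FALSE)
    anchors <- which(ctg$gene_id %in% c(ev$rid_gene_id[i], ev$partner_gene_id[i]))
    any(vapply(comp, function(ci) {
      any(abs(ranks[ci] - ranks[anchors]) - 1L <= max_intervening)
    }, logical(1)))
  }, logical(1))
  mean(hit)
}
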