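#' Karlin-Altschul expectation value
#'
#' E = K * m * n * exp(-lambda * S) for a local alignment of raw score S
#' between sequences of lengths m and n. Defaults are the published
#' gapped-BLOSUM62 constants (gap open 11 / extend 1).
#'
#' @param score Raw alignment score S.
#' @param m,n Query and target sequence lengths.
#' @param lambda,K Karlin-Altschul parameters (defaults 0.267, 0.041).
#' @return Expectation value (strictly decreasing in `score`).
#' @export
karlin_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  K * m * n * exp(-lambda * score)
}

# unique k-mers of a sequence (character vector)
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Find Rid-family candidates by seeded local alignment
#'
#' Exact shared k-mers between a query and a proteome sequence seed a local
#' Smith-Waterman alignment (BLOSUM62, gap open 11 / extend 1); a hit is
#' retained iff its Karlin-Altschul expectation
#' E = K * m * n * exp(-lambda * S) is at or below `evalue_cutoff`
#' (the relaxed 1e-4 cutoff used for exhaustive family detection). One best
#' hit per (query, target) pair.
#'
#' @param queries Named character vector of query protein sequences.
#' @param proteome Named character vector of target protein sequences.
#' @param kmer_k Seed word length (>= 3; default 4).
#' @param evalue_cutoff Maximum E-value retained (default 1e-4).
#' @param gap_open,gap_extend Gap penalties (defaults 11, 1).
#' @param lambda,K Karlin-Altschul constants (defaults 0.267, 0.041).
#' @return Data frame: query_id, target_id, raw_score, evalue, target_start,
#'   target_end. Empty proteome gives an empty data frame.
#' @export
find_candidates <- function(queries, proteome, kmer_k = 4L,
                            evalue_cutoff = 1e-4,
                            gap_open = 11, gap_extend = 1,
                            lambda = 0.267, K = 0.041) {
  if (kmer_k < 3L) stop("kmer_k must be >= 3")
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be > 0")
  empty <- data.frame(query_id = character(0), target_id = character(0),
                      raw_score = numeric(0), evalue = numeric(0),
                      target_start = integer(0), target_end = integer(0))
  if (length(proteome) == 0L) return(empty)
  if (length(queries) == 0L) return(empty)
  if (min(nchar(queries)) < kmer_k) {
    stop("kmer_k exceeds the shortest query length")
  }
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  blosum <- get("BLOSUM62", envir = data_env)

  qk <- lapply(queries, seq_kmers, k = kmer_k)
  tk <- lapply(proteome, seq_kmers, k = kmer_k)
  out <- vector("list", length(queries) * length(proteome))
  pos <- 0L
  for (qi in seq_along(queries)) {
    for (ti in seq_along(proteome)) {
      if (!any(qk[[qi]] %in% tk[[ti]])) next  # no seed, no alignment
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(queries[[qi]]),
        Biostrings::AAString(proteome[[ti]]),
        type = "local", substitutionMatrix = blosum,
        gapOpening = gap_open, gapExtension = gap_extend)
      S <- Biostrings::score(pa)
      ev <- karlin_evalue(S, nchar(queries[[qi]]), nchar(proteome[[ti]]),
                          lambda, K)
      if (ev > evalue_cutoff) next
      sbj <- Biostrings::subject(pa)
      pos <- pos + 1L
      out[[pos]] <- data.frame(
        query_id = names(queries)[[qi]], target_id = names(proteome)[[ti]],
        raw_score = S, evalue = ev,
        target_start = Biostrings::start(sbj), target_end = Biostrings::end(sbj))
    }
  }
  if (pos == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(pos)])
  rownames(res) <- NULL
  res
}

# integer residue indices into aa_alphabet(); NA for 'X' (scores 0)
aa_index <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], aa_alphabet())
}

# all gapless window scores of a profile along a protein: numeric vector
# indexed by offset (length L - W + 1), or NULL when the protein is shorter
# than the profile
window_scores <- function(idx, profile) {
  L <- length(idx)
  W <- profile$length
  if (L < W) return(NULL)
  n_off <- L - W + 1L
  pos <- rep(seq_len(n_off), times = W) + rep(0:(W - 1L), each = n_off)
  sc <- profile$scores[cbind(rep(seq_len(W), each = n_off), idx[pos])]
  sc[is.na(sc)] <- 0  # 'X' is neutral
  rowSums(matrix(sc, nrow = n_off))
}

domain_hit <- function(protein_id, profile, seq, idx, offset, total) {
  cols <- seq_len(profile$length)
  at <- offset + cols - 1L
  colsc <- profile$scores[cbind(cols, idx[at])]
  colsc[is.na(colsc)] <- 0
  region_scores <- NULL
  if (!is.null(profile$footprints)) {
    region_scores <- vapply(seq_len(nrow(profile$footprints)), function(i) {
      r <- profile$footprints[i, ]
      sum(colsc[seq.int(r$start, r$end)])
    }, numeric(1))
    names(region_scores) <- paste0("region", profile$footprints$index)
  }
  key_residues <- NULL
  if (!is.null(profile$key_sites)) {
    kpos <- offset + profile$key_sites - 1L
    key_residues <- vapply(kpos, function(p) {
      if (p >= 1L && p <= nchar(seq)) substr(seq, p, p) else NA_character_
    }, character(1))
    names(key_residues) <- names(profile$key_sites)
  }
  structure(
    list(protein_id = protein_id, subfamily = profile$subfamily,
         offset = as.integer(offset), total_score = total,
         region_scores = region_scores, key_residues = key_residues),
    class = "rid_domain_hit")
}

#' Scan a protein against all subfamily profiles
#'
#' Gapless sliding window of each profile over every offset of the protein;
#' the best-scoring window per profile is returned (ties broken by the
#' smallest offset). 'X' residues contribute 0 bits.
#'
#' @param protein Named length-1 character vector, or a character string
#'   plus `protein_id`.
#' @param profiles List of `rid_profile` objects.
#' @param protein_id Protein identifier (defaults to `names(protein)`).
#' @return Named list of `rid_domain_hit` per subfamily; profiles longer
#'   than the protein are skipped (empty list plus a warning when all are).
#' @export
scan_subfamilies <- function(protein, profiles, protein_id = names(protein)) {
  seq <- toupper(as.character(protein[[1L]]))
  if (is.null(protein_id)) protein_id <- "protein"
  idx <- aa_index(seq)
  hits <- list()
  for (p in profiles) {
    ws <- window_scores(idx, p)
    if (is.null(ws)) next
    best <- which.max(ws)  # first max = smallest offset on ties
    hits[[p$subfamily]] <- domain_hit(protein_id, p, seq, idx, best, ws[[best]])
  }
  if (length(hits) == 0L) {
    warning("protein '", protein_id, "' shorter than every profile")
  }
  hits
}

#' Assign a subfamily from per-subfamily domain hits
#'
#' The best-scoring subfamily wins if its score reaches `score_threshold`
#' and beats the runner-up by at least `margin_threshold`; otherwise the
#' protein is UNCLASSIFIED (the false-positive filter). Exact ties are
#' broken by the fixed subfamily order RidA < Rid1 < ... < Rid7 and flagged.
#'
#' @param hits Named list of `rid_domain_hit` (as from [scan_subfamilies()]).
#' @param score_threshold Minimum winning score in bits; either a single
#'   number or a named per-subfamily vector (see
#'   [default_score_thresholds()]).
#' @param margin_threshold Minimum best-minus-runner-up margin in bits
#'   (default 0).
#' @return Object of class `rid_classification`: protein_id, assigned
#'   (subfamily or "UNCLASSIFIED"), best_score, margin, arg_site_residue,
#'   tyr_site_residue, glu_site_residue, hydrolase_competent,
#'   atypical_serine, tie.
#' @export
assign_subfamily <- function(hits, score_threshold, margin_threshold = 0) {
  if (length(hits) == 0L) {
    return(structure(
      list(protein_id = NA_character_, assigned = "UNCLASSIFIED",
           best_score = 0, margin = 0, arg_site_residue = NA_character_,
           tyr_site_residue = NA_character_, glu_site_residue = NA_character_,
           hydrolase_competent = NA, atypical_serine = NA, tie = FALSE),
      class = "rid_classification"))
  }
  order_all <- rid_subfamilies()
  fams <- names(hits)
  ord <- order(match(fams, order_all, nomatch = length(order_all) + 1L))
  hits <- hits[ord]
  fams <- names(hits)
  scores <- vapply(hits, function(h) h$total_score, numeric(1))
  best_i <- which.max(scores)  # first max follows subfamily order
  best <- scores[[best_i]]
  runner <- if (length(scores) > 1L) max(scores[-best_i]) else -Inf
  margin <- if (is.finite(runner)) best - runner else best
  tie <- sum(scores == best) > 1L
  thr <- if (!is.null(names(score_threshold)) && fams[[best_i]] %in% names(score_threshold)) {
    score_threshold[[fams[[best_i]]]]
  } else {
    score_threshold[[1L]]
  }
  win <- hits[[best_i]]
  classified <- best >= thr && margin >= margin_threshold
  kr <- win$key_residues
  arg <- if (classified && !is.null(kr)) kr[["arg"]] else NA_character_
  tyr <- if (classified && !is.null(kr)) kr[["tyr"]] else NA_character_
  glu <- if (classified && !is.null(kr)) kr[["glu"]] else NA_character_
  assigned <- if (classified) fams[[best_i]] else "UNCLASSIFIED"
  structure(
    list(protein_id = win$protein_id,
         assigned = assigned,
         best_score = best,
         margin = max(margin, 0),
         arg_site_residue = arg,
         tyr_site_residue = tyr,
         glu_site_residue = glu,
         hydrolase_competent = if (classified) identical(arg, "R") else NA,
         atypical_serine = if (classified) {
           identical(assigned, "RidA") && identical(arg, "S")
         } else NA,
         tie = tie),
    class = "rid_classification")
}

#' Default per-subfamily score thresholds
#'
#' Half the consensus self-score of each profile - a window must recover at
#' least 50% of the maximal attainable information to count as that
#' subfamily.
#'
#' @param profiles List of `rid_profile`.
#' @param fraction Fraction of the consensus self-score (default 0.5).
#' @return Named numeric vector of thresholds in bits.
#' @export
default_score_thresholds <- function(profiles, fraction = 0.5) {
  vapply(profiles, function(p) fraction * profile_max_score(p), numeric(1)) |>
    stats::setNames(vapply(profiles, function(p) p$subfamily, character(1)))
}

#' Call active-site residues from a domain hit
#'
#' Key-site protein positions are offset + key column - 1. An arginine at
#' the arg site predicts imine-hydrolase competence; serine there within
#' RidA flags the atypical ~10% minority. Positions beyond the protein
#' (truncated ORFs) are reported missing with unknown competence.
#'
#' @param protein Protein sequence (length-1 character).
#' @param hit A `rid_domain_hit` on that protein.
#' @return List: arg_site_residue, tyr_site_residue, glu_site_residue,
#'   hydrolase_competent (NA when the arg site is missing), atypical_serine.
#' @export
call_active_site <- function(protein, hit) {
  seq <- toupper(as.character(protein[[1L]]))
  stopifnot(inherits(hit, "rid_domain_hit"))
  kr <- hit$key_residues
  if (is.null(kr)) stop("hit has no key residues (profile lacked key sites)")
  arg <- kr[["arg"]]
  list(arg_site_residue = arg,
       tyr_site_residue = kr[["tyr"]],
       glu_site_residue = kr[["glu"]],
       hydrolase_competent = if (is.na(arg)) NA else identical(arg, "R"),
       atypical_serine = if (is.na(arg)) NA else {
         identical(hit$subfamily, "RidA") && identical(arg, "S")
       })
}

#' Detect tandem Rid-domain fusions
#'
#' All profile windows scoring at least the (per-subfamily) threshold are
#' collected and a maximal set of non-overlapping windows is chosen greedily
#' in decreasing score order (ties: smaller offset, then subfamily order).
#' Three selected RidA domains flag the 3x-RidA arrangement.
#'
#' @param protein Protein sequence (length-1, optionally named).
#' @param profiles List of `rid_profile`.
#' @param score_threshold Single number or named per-subfamily vector of
#'   minimum window scores in bits.
#' @param protein_id Protein identifier.
#' @return Object of class `rid_fusion_call`: protein_id, domain_count,
#'   intervals (data frame: start, end, subfamily, score), is_3x, not_rid.
#' @export
detect_fusion <- function(protein, profiles, score_threshold,
                          protein_id = names(protein)) {
  seq <- toupper(as.character(protein[[1L]]))
  if (is.null(protein_id)) protein_id <- "protein"
  idx <- aa_index(seq)
  wins <- list()
  for (p in profiles) {
    ws <- window_scores(idx, p)
    if (is.null(ws)) next
    thr <- if (!is.null(names(score_threshold)) && p$subfamily %in% names(score_threshold)) {
      score_threshold[[p$subfamily]]
    } else {
      score_threshold[[1L]]
    }
    ok <- which(ws >= thr)
    if (length(ok) == 0L) next
    wins[[length(wins) + 1L]] <- data.frame(
      start = ok, end = ok + p$length - 1L, subfamily = p$subfamily,
      score = ws[ok])
  }
  intervals <- data.frame(start = integer(0), end = integer(0),
                          subfamily = character(0), score = numeric(0))
  if (length(wins)) {
    cand <- do.call(rbind, wins)
    cand <- cand[order(-cand$score, cand$start,
                       match(cand$subfamily, rid_subfamilies())), ]
    taken <- logical(nchar(seq))
    for (i in seq_len(nrow(cand))) {
      span <- cand$start[i]:cand$end[i]
      if (!any(taken[span])) {
        taken[span] <- TRUE
        intervals <- rbind(intervals, cand[i, ])
      }
    }
    intervals <- intervals[order(intervals$start), ]
    rownames(intervals) <- NULL
  }
  n <- nrow(intervals)
  structure(
    list(protein_id = protein_id,
         domain_count = n,
         intervals = intervals,
         is_3x = n == 3L && all(intervals$subfamily == "RidA"),
         not_rid = n == 0L),
    class = "rid_fusion_call")
}

#' Classify a whole proteome
#'
#' Runs [scan_subfamilies()], [assign_subfamily()] and [detect_fusion()]
#' over every protein and returns the fixed-column classification table.
#'
#' @param proteome Data frame with columns protein_id, genome_id, sequence
#'   (or a named character vector; genome_id then parsed from
#'   "genome|protein" ids).
#' @param profiles List of `rid_profile`.
#' @param score_threshold,margin_threshold See [assign_subfamily()];
#'   `score_threshold` defaults to [default_score_thresholds()].
#' @return Data frame with columns protein_id, genome_id, subfamily, score,
#'   margin, arg_site_residue, competent, atypical, fusion_count (fixed
#'   order).
#' @export
classify_proteome <- function(proteome, profiles,
                              score_threshold = default_score_thresholds(profiles),
                              margin_threshold = 0) {
  if (is.character(proteome)) {
    ids <- names(proteome)
    proteome <- data.frame(
      protein_id = ids,
      genome_id = ifelse(grepl("|", ids, fixed = TRUE),
                         sub("\\|.*$", "", ids), NA_character_),
      sequence = unname(proteome))
  }
  proteome <- proteome[order(proteome$protein_id), , drop = FALSE]
  if (nrow(proteome) == 0L) {
    return(data.frame(protein_id = character(0), genome_id = character(0),
                      subfamily = character(0), score = numeric(0),
                      margin = numeric(0), arg_site_residue = character(0),
                      competent = logical(0), atypical = logical(0),
                      fusion_count = integer(0)))
  }
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    pid <- proteome$protein_id[[i]]
    seq <- proteome$sequence[[i]]
    hits <- suppressWarnings(scan_subfamilies(seq, profiles, protein_id = pid))
    cls <- assign_subfamily(hits, score_threshold, margin_threshold)
    fus <- if (identical(cls$assigned, "UNCLASSIFIED")) NULL else {
      detect_fusion(seq, profiles, score_threshold, protein_id = pid)
    }
    data.frame(protein_id = pid,
               genome_id = proteome$genome_id[[i]],
               subfamily = cls$assigned,
               score = cls$best_score,
               margin = cls$margin,
               arg_site_residue = if (is.na(cls$arg_site_residue)) "-" else cls$arg_site_residue,
               competent = isTRUE(cls$hydrolase_competent),
               atypical = isTRUE(cls$atypical_serine),
               fusion_count = if (is.null(fus)) 0L else fus$domain_count)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
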