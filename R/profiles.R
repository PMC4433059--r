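#' Build a position-specific scoring profile from a subfamily seed alignment
#'
#' Columns with more than `gap_threshold` gaps are dropped (trimming), then
#' each remaining column c is scored for every residue a as
#' \deqn{score(c,a) = \log_2\frac{(n_{c,a} + \beta q_a)/(N_c + \beta)}{q_a}}
#' where \eqn{n_{c,a}} is the count of residue a in column c, \eqn{N_c} the
#' non-gap count, \eqn{q_a} the background frequency and \eqn{\beta} the
#' total pseudocount mass split by background. Footprint regions and key
#' catalytic sites (tyr/arg/glu, TdcF numbering homologs) are supplied in
#' original alignment coordinates and re-mapped to trimmed coordinates.
#'
#' @param alignment A [rid_alignment][new_alignment].
#' @param subfamily Subfamily label (one of [rid_subfamilies()], or any
#'   label for ad-hoc profiles).
#' @param background Per-residue background frequencies over [aa_alphabet()]
#'   (must sum to 1); default uniform 1/20.
#' @param pseudocount_mass Total pseudocount mass beta > 0 (default 1).
#' @param footprints Data frame with columns `index`, `start`, `end` giving
#'   the (up to six) conserved footprint regions in alignment coordinates,
#'   or NULL.
#' @param key_sites Named integer vector with elements `tyr`, `arg`, `glu`
#'   (alignment column indices), or NULL.
#' @param gap_threshold Columns with a gap fraction strictly above this are
#'   trimmed (default 0.5).
#' @return An object of class `rid_profile`: `subfamily`, `length`, `scores`
#'   (length x 20 matrix, bits), `frequencies` (raw non-gap column
#'   frequencies), `background`, `pseudocount_mass`, `footprints` (remapped),
#'   `key_sites` (remapped), `kept_columns` (original indices of surviving
#'   columns).
#' @export
build_profile <- function(alignment, subfamily,
                          background = rep(1 / 20, 20),
                          pseudocount_mass = 1,
                          footprints = NULL,
                          key_sites = NULL,
                          gap_threshold = 0.5) {
  stopifnot(inherits(alignment, "rid_alignment"))
  if (!is.numeric(pseudocount_mass) || length(pseudocount_mass) != 1L ||
      pseudocount_mass <= 0) {
    stop("pseudocount_mass must be a single value > 0")
  }
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("background must be 20 positive frequencies summing to 1")
  }
  background <- as.numeric(background)
  names(background) <- aa_alphabet()

  m <- alignment_matrix(alignment)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= gap_threshold)
  if (length(keep) == 0L) {
    stop("degenerate input: all ", ncol(m), " columns exceed the ",
         gap_threshold, " gap threshold")
  }
  # original column -> trimmed column; NA for trimmed
  colmap <- rep(NA_integer_, ncol(m))
  colmap[keep] <- seq_along(keep)

  mk <- m[, keep, drop = FALSE]
  alpha <- aa_alphabet()
  counts <- vapply(seq_len(ncol(mk)), function(j) {
    col <- mk[, j]
    tabulate(factor(col[col != "-" & col != "X"], levels = alpha), 20L)
  }, numeric(20))           # 20 x length
  N <- colSums(counts)      # non-gap (and non-X) count per column
  beta <- pseudocount_mass
  smoothed <- sweep(counts + beta * background, 2L, N + beta, "/")  # 20 x L
  scores <- t(log2(smoothed / background))                          # L x 20
  colnames(scores) <- alpha
  freqs <- t(sweep(counts, 2L, pmax(N, 1), "/"))
  colnames(freqs) <- alpha

  ks <- NULL
  if (!is.null(key_sites)) {
    need <- c("tyr", "arg", "glu")
    if (!all(need %in% names(key_sites))) {
      stop("key_sites must be named with tyr, arg, glu")
    }
    key_sites <- as.integer(key_sites[need])
    if (any(key_sites < 1L | key_sites > ncol(m))) {
      stop("key_sites outside alignment columns [1, ", ncol(m), "]")
    }
    mapped <- colmap[key_sites]
    if (anyNA(mapped)) {
      bad <- need[is.na(mapped)]
      stop("key site(s) ", paste(bad, collapse = ", "),
           " fall in trimmed column(s) ",
           paste(key_sites[is.na(mapped)], collapse = ", "))
    }
    ks <- stats::setNames(mapped, need)
  }

  fp <- NULL
  if (!is.null(footprints)) {
    fp <- remap_footprints(footprints, colmap)
  }

  prof <- structure(
    list(subfamily = subfamily,
         length = length(keep),
         scores = scores,
         frequencies = freqs,
         n_effective = N,
         background = background,
         pseudocount_mass = beta,
         footprints = fp,
         key_sites = ks,
         kept_columns = keep),
    class = "rid_profile"
  )
  validate_profile(prof)
  prof
}

remap_footprints <- function(footprints, colmap) {
  stopifnot(all(c("index", "start", "end") %in% names(footprints)))
  fp <- footprints[order(footprints$start), , drop = FALSE]
  if (nrow(fp) > 1L && any(fp$start[-1L] <= fp$end[-nrow(fp)])) {
    stop("footprint regions overlap")
  }
  out <- lapply(seq_len(nrow(fp)), function(i) {
    cols <- seq.int(fp$start[i], fp$end[i])
    mapped <- colmap[cols]
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped) == 0L) return(NULL)
    data.frame(index = fp$index[i], start = min(mapped), end = max(mapped))
  })
  dropped <- vapply(out, is.null, logical(1))
  if (any(dropped)) {
    warning("footprint region(s) ", paste(fp$index[dropped], collapse = ", "),
            " fully trimmed; dropped")
  }
  do.call(rbind, out[!dropped])
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "rid_profile"))
  if (p$length < 1L) stop("profile has no columns")
  if (abs(sum(p$background) - 1) > 1e-9) stop("background does not sum to 1")
  if (!is.null(p$key_sites) &&
      any(p$key_sites < 1L | p$key_sites > p$length)) {
    stop("key sites outside [1, length]")
  }
  if (!is.null(p$footprints) && nrow(p$footprints) > 1L) {
    fp <- p$footprints[order(p$footprints$start), ]
    if (any(fp$start[-1L] <= fp$end[-nrow(fp)])) {
      stop("footprint regions overlap after remapping")
    }
  }
  invisible(p)
}

#' @export
print.rid_profile <- function(x, ...) {
  cat("rid_profile '", x$subfamily, "': ", x$length, " columns, beta=",
      x$pseudocount_mass, "\n", sep = "")
  if (!is.null(x$key_sites)) {
    cat("  key sites (trimmed coords): tyr=", x$key_sites[["tyr"]],
        " arg=", x$key_sites[["arg"]], " glu=", x$key_sites[["glu"]],
        "\n", sep = "")
  }
  invisible(x)
}

#' Per-column conservation (sequence-logo) statistics
#'
#' For every alignment column, residue frequencies over the non-gap residues
#' and the information content in bits,
#' \eqn{IC = \log_2 20 - H} with H the Shannon entropy of the frequencies.
#' Letter height for rendering is frequency x information_bits. No
#' small-sample correction is applied.
#'
#' @param alignment A [rid_alignment][new_alignment].
#' @return Object of class `rid_logo`: `frequencies` (n_columns x 20),
#'   `information_bits` (numeric), `all_gap` (logical flag per column;
#'   all-gap columns report 0 bits).
#' @export
conservation_logo <- function(alignment) {
  stopifnot(inherits(alignment, "rid_alignment"))
  m <- alignment_matrix(alignment)
  alpha <- aa_alphabet()
  counts <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    tabulate(factor(col[col != "-" & col != "X"], levels = alpha), 20L)
  }, numeric(20))
  N <- colSums(counts)
  all_gap <- N == 0
  freqs <- sweep(counts, 2L, pmax(N, 1), "/")   # 20 x C
  H <- apply(freqs, 2L, function(f) {
    f <- f[f > 0]
    if (length(f) == 0L) return(0)
    -sum(f * log2(f))
  })
  bits <- log2(20) - H
  bits[all_gap] <- 0
  structure(
    list(frequencies = t(freqs), information_bits = as.numeric(bits),
         all_gap = all_gap, n_columns = ncol(m)),
    class = "rid_logo"
  )
}

#' Export logo data as long-format TSV
#'
#' One row per (column, residue) with non-zero frequency: column, residue,
#' frequency, bits (the letter height, frequency x column information).
#'
#' @param logo A `rid_logo` from [conservation_logo()].
#' @param path Output TSV path.
#' @return The exported data frame, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  stopifnot(inherits(logo, "rid_logo"))
  alpha <- aa_alphabet()
  rows <- lapply(seq_len(logo$n_columns), function(j) {
    f <- logo$frequencies[j, ]
    nz <- which(f > 0)
    if (length(nz) == 0L) return(NULL)
    data.frame(column = j, residue = alpha[nz], frequency = f[nz],
               bits = f[nz] * logo$information_bits[j])
  })
  df <- do.call(rbind, rows)
  write_tsv_strict(df, path)
  invisible(df)
}

#' Footprint-region consensus and key-site residue summary
#'
#' For each footprint region the maximum-frequency residue per column (ties
#' broken by the lexicographically smallest residue and flagged), and for
#' the catalytic arginine site the full ranked residue-frequency spectrum
#' (this is how the ~10% serine minority within RidA is surfaced).
#'
#' @param profile A `rid_profile` with footprints and key sites.
#' @return List with `regions` (data frame: index, column, consensus,
#'   frequency, tie) and `arg_site` (named numeric vector of residue
#'   frequencies at the arg site, decreasing).
#' @export
footprint_consensus <- function(profile) {
  validate_profile(profile)
  if (is.null(profile$footprints)) stop("profile has no footprint regions")
  if (is.null(profile$key_sites)) stop("profile has no key sites")
  alpha <- aa_alphabet()
  cons_one <- function(col) {
    f <- profile$frequencies[col, ]
    mx <- max(f)
    winners <- alpha[f == mx]
    data.frame(column = col, consensus = winners[[1L]], frequency = mx,
               tie = length(winners) > 1L)
  }
  regions <- do.call(rbind, lapply(seq_len(nrow(profile$footprints)), function(i) {
    r <- profile$footprints[i, ]
    df <- do.call(rbind, lapply(seq.int(r$start, r$end), cons_one))
    df$index <- r$index
    df[, c("index", "column", "consensus", "frequency", "tie")]
  }))
  argf <- profile$frequencies[profile$key_sites[["arg"]], ]
  argf <- argf[argf > 0]
  argf <- argf[order(-argf, names(argf))]
  list(regions = regions, arg_site = argf)
}

#' Consensus sequence of a profile
#'
#' Per-column argmax of the score matrix; ties broken by the
#' lexicographically smallest residue. By construction this sequence attains
#' the maximal achievable per-column score at every column.
#'
#' @param profile A `rid_profile`.
#' @return Single character string of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  validate_profile(profile)
  alpha <- aa_alphabet()
  idx <- apply(profile$scores, 1L, which.max)
  paste(alpha[idx], collapse = "")
}

#' Maximal attainable score of a profile (consensus self-score)
#'
#' @param profile A `rid_profile`.
#' @return Sum over columns of the per-column maximum score, in bits.
#' @export
profile_max_score <- function(profile) {
  sum(apply(profile$scores, 1L, max))
}

#' Serialize a profile to a versioned JSON document
#'
#' @param profile A `rid_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  doc <- list(
    format = "ridscape-profile",
    version = 1L,
    subfamily = profile$subfamily,
    length = profile$length,
    alphabet = aa_alphabet(),
    background = as.numeric(profile$background),
    pseudocount_mass = profile$pseudocount_mass,
    scores = unname(apply(profile$scores, 1L, as.numeric, simplify = FALSE)),
    frequencies = unname(apply(profile$frequencies, 1L, as.numeric,
                               simplify = FALSE)),
    n_effective = as.numeric(profile$n_effective),
    footprints = profile$footprints,
    key_sites = as.list(profile$key_sites),
    kept_columns = profile$kept_columns
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized profile
#'
#' @param path Path written by [write_profile()].
#' @return A `rid_profile`.
#' @export
read_profile <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ridscape-profile")) {
    stop("not a ridscape profile document: ", path)
  }
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  scores <- as_mat(doc$scores)
  freqs <- as_mat(doc$frequencies)
  colnames(scores) <- colnames(freqs) <- aa_alphabet()
  prof <- structure(
    list(subfamily = doc$subfamily,
         length = as.integer(doc$length),
         scores = scores,
         frequencies = freqs,
         n_effective = as.numeric(doc$n_effective),
         background = stats::setNames(as.numeric(doc$background), aa_alphabet()),
         pseudocount_mass = doc$pseudocount_mass,
         footprints = if (length(doc$footprints)) as.data.frame(doc$footprints) else NULL,
         key_sites = if (length(doc$key_sites)) unlist(doc$key_sites) else NULL,
         kept_columns = as.integer(doc$kept_columns)),
    class = "rid_profile"
  )
  validate_profile(prof)
  prof
}
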