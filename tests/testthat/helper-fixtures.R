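# Shared fixtures, built in code. Heavy objects are memoised so several
# test files can reuse one synthetic world.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default study-condition world (200 genomes, divergence 0.05,
# indel-free) plus its profiles and full classification
default_world <- function() {
  memo("default_world", function() {
    w <- generate_world(world_config(seed = 424242L, n_genomes = 200L))
    profs <- world_profiles(w)
    cls <- classify_proteome(w$proteome, profs)
    list(world = w, profiles = profs, classification = cls)
  })
}

small_world <- function() {
  memo("small_world", function() {
    w <- generate_world(world_config(seed = 99L, n_genomes = 12L))
    list(world = w, profiles = world_profiles(w))
  })
}

# a tiny ungapped alignment with known column composition
toy_alignment <- function() {
  new_alignment("toy", c(
    s1 = "ARNDC",
    s2 = "ARNDC",
    s3 = "ARNDC",
    s4 = "CRNDA"))
}

# brute-force oracle: best gapless window of a profile on a protein,
# summing per-column scores one offset at a time
oracle_best_window <- function(seq, profile) {
  idx <- match(strsplit(seq, "")[[1L]], aa_alphabet())
  L <- length(idx)
  W <- profile$length
  if (L < W) return(NULL)
  best <- list(offset = NA_integer_, score = -Inf)
  for (off in seq_len(L - W + 1L)) {
    sc <- profile$scores[cbind(seq_len(W), idx[off + seq_len(W) - 1L])]
    sc[is.na(sc)] <- 0
    total <- sum(sc)
    if (total > best$score) best <- list(offset = off, score = total)
  }
  best
}

# brute-force oracle: best pair of non-overlapping above-threshold windows
oracle_best_pair <- function(seq, profile, threshold) {
  idx <- match(strsplit(seq, "")[[1L]], aa_alphabet())
  L <- length(idx)
  W <- profile$length
  offs <- seq_len(L - W + 1L)
  scores <- vapply(offs, function(off) {
    sc <- profile$scores[cbind(seq_len(W), idx[off + seq_len(W) - 1L])]
    sc[is.na(sc)] <- 0
    sum(sc)
  }, numeric(1))
  ok <- offs[scores >= threshold]
  best <- NULL
  for (a in ok) for (b in ok) {
    if (b >= a + W) {
      tot <- scores[a] + scores[b]
      if (is.null(best) || tot > best$total) {
        best <- list(starts = c(a, b), total = tot)
      }
    }
  }
  best
}

# brute-force single-linkage oracle: transitive closure of the
# threshold graph via repeated boolean expansion
oracle_components <- function(distances, cutoff) {
  adj <- (distances <= cutoff)
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  ids <- rownames(distances)
  comps <- unique(lapply(seq_len(nrow(reach)), function(i) sort(ids[reach[i, ]])))
  comps[order(vapply(comps, `[[`, character(1), 1L))]
}

random_distance_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- sprintf("g%02d", seq_len(n))
  m
}

# a 6-gene toy contig: one RidA gene, one ACT two genes away, one OCT
# seven genes away would not fit on six genes, so the OCT is placed past
# the intervening budget instead
toy_contig <- function() {
  data.frame(
    genome_id = "tg1", contig = "c1",
    gene_id = paste0("t", 1:6),
    start = c(100, 700, 1500, 2300, 3100, 20000),
    end = c(500, 1300, 2100, 2900, 3700, 21000),
    strand = c("+", "+", "-", "+", "+", "-"),
    role = c("RID:RidA", "OTHER", "OTHER", "ACT", "OTHER", "OCT"))
}
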