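test_that("cluster events honor the intervening/gap window and contigs", {
  feats <- data.frame(
    genome_id = "g1", contig = "c1",
    gene_id = c("rid1", "act1"),
    start = c(100, 600), end = c(500, 1200),
    strand = c("+", "+"),
    role = c("RID:RidA", "ACT"))
  ev <- find_cluster_events(feats)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$intervening_genes, 0L)
  expect_equal(ev$gap_bp, 99L)   # 600 - 500 - 1
  expect_true(ev$same_strand)
  # different contigs never cluster
  feats2 <- feats
  feats2$contig <- c("c1", "c2")
  expect_equal(nrow(find_cluster_events(feats2)), 0L)
  # strand policies
  feats3 <- feats
  feats3$strand <- c("+", "-")   # convergent -> <-
  expect_equal(nrow(find_cluster_events(feats3, strand_policy = "same")), 0L)
  expect_equal(nrow(find_cluster_events(feats3, strand_policy = "divergent_ok")), 0L)
  feats3$strand <- c("-", "+")   # divergent <- ->
  expect_equal(nrow(find_cluster_events(feats3, strand_policy = "divergent_ok")), 1L)
  # malformed coordinates are a record-level error naming the gene
  feats4 <- feats
  feats4$end[1] <- 50
  expect_error(find_cluster_events(feats4), "rid1")
})

test_that("toy contig events match exhaustive pair enumeration", {
  feats <- toy_contig()
  ev <- find_cluster_events(feats)
  # brute force over all (rid, partner) pairs with the same thresholds
  ctg <- feats[order(feats$start), ]
  expected <- 0L
  for (i in which(startsWith(ctg$role, "RID:"))) {
    for (j in which(ctg$role %in% c("ACT", "OCT"))) {
      intervening <- abs(i - j) - 1L
      gap <- max(0L, max(ctg$start[i], ctg$start[j]) -
                   min(ctg$end[i], ctg$end[j]) - 1L)
      if (intervening <= 3L && gap <= 5000L) expected <- expected + 1L
    }
  }
  expect_equal(nrow(ev), expected)
  expect_equal(nrow(ev), 1L)         # only the ACT two genes away
  expect_equal(ev$partner_role, "ACT")
  expect_equal(ev$intervening_genes, 2L)
})

test_that("events are invariant to feature order and mirror transform", {
  sw <- small_world()
  feats <- sw$world$features
  ev <- find_cluster_events(feats)
  # shuffled input
  set.seed(3)
  ev_shuf <- find_cluster_events(feats[sample(nrow(feats)), ])
  expect_equal(ev_shuf, ev)
  # mirror: reverse coordinates per contig
  mirrored <- feats
  for (ctg in unique(feats$contig)) {
    sel <- feats$contig == ctg
    m <- max(feats$end[sel]) + 1L
    s <- m - feats$end[sel]
    e <- m - feats$start[sel]
    mirrored$start[sel] <- s
    mirrored$end[sel] <- e
    mirrored$strand[sel] <- ifelse(feats$strand[sel] == "+", "-", "+")
  }
  ev_mir <- find_cluster_events(mirrored)
  key <- function(d) {
    o <- order(d$rid_gene_id, d$partner_gene_id)
    d[o, c("rid_gene_id", "partner_gene_id", "intervening_genes", "gap_bp")]
  }
  expect_equal(unname(key(ev_mir)), unname(key(ev)))
})

test_that("pie frequencies are proportions that sum to one per role", {
  mk_ev <- function(subfams, role) {
    data.frame(genome_id = "g1", contig = "c1",
               rid_gene_id = paste0("r", seq_along(subfams)),
               rid_subfamily = subfams,
               partner_gene_id = paste0("p", seq_along(subfams)),
               partner_role = role, intervening_genes = 0L,
               gap_bp = 10L, same_strand = TRUE)
  }
  # all RidA
  expect_equal(subfamily_frequencies(mk_ev(rep("RidA", 4), "ACT"))$frequency, 1)
  # 8 RidA + 2 Rid7 -> 0.8 / 0.2, the "about 80%" structure
  sf <- subfamily_frequencies(mk_ev(c(rep("RidA", 8), rep("Rid7", 2)), "ACT"))
  expect_equal(sf$frequency[sf$subfamily == "RidA"], 0.8)
  expect_equal(sf$frequency[sf$subfamily == "Rid7"], 0.2)
  expect_equal(sum(sf$frequency), 1)
  # empty event list -> empty summary
  expect_equal(nrow(subfamily_frequencies(mk_ev(rep("RidA", 4), "ACT")[0, ])), 0L)
  # per-role normalization on the synthetic world
  ev <- find_cluster_events(small_world()$world$features)
  sf2 <- subfamily_frequencies(ev)
  sums <- tapply(sf2$frequency, sf2$role, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("genome proportions count genomes once and reject stray events", {
  ev <- data.frame(genome_id = c("g1", "g1", "g2", "g3", "g4", "g5"),
                   contig = "c1", rid_gene_id = paste0("r", 1:6),
                   rid_subfamily = "RidA",
                   partner_gene_id = paste0("p", 1:6),
                   partner_role = "ACT", intervening_genes = 0L,
                   gap_bp = 1L, same_strand = TRUE)
  out <- role_genome_proportions(ev, paste0("g", 1:10))
  expect_equal(out$proportion, 0.5)   # 5 of 10 genomes
  expect_equal(out$instance_count, 6L)
  # role with no events reports zero when asked for
  out2 <- role_genome_proportions(ev, paste0("g", 1:10), roles = c("ACT", "OCT"))
  expect_equal(out2$proportion[out2$role == "OCT"], 0)
  expect_equal(out2$instance_count[out2$role == "OCT"], 0L)
  expect_error(role_genome_proportions(ev, paste0("g", 1:3)), "outside")
  expect_error(role_genome_proportions(ev, character(0)), "non-empty")
})

test_that("co-clustering fraction finds companion subfamilies near clusters", {
  base <- data.frame(
    genome_id = "g1", contig = "c1",
    gene_id = c("r7", "act", "rA"),
    start = c(100, 600, 1300), end = c(500, 1200, 1700),
    strand = "+",
    role = c("RID:Rid7", "ACT", "RID:RidA"))
  ev <- find_cluster_events(base)
  ev7 <- ev[ev$rid_subfamily == "Rid7", ]
  expect_equal(co_cluster_fraction(ev7, base, "Rid7", "RidA"), 1.0)
  # companion removed -> 0
  no_comp <- base[base$gene_id != "rA", ]
  ev0 <- find_cluster_events(no_comp)
  expect_equal(co_cluster_fraction(ev0, no_comp, "Rid7", "RidA"), 0.0)
  # no focal events -> missing, not zero
  res <- co_cluster_fraction(ev0[0, ], base, "Rid7", "RidA")
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "no focal events")
  expect_error(co_cluster_fraction(ev0, base, "Rid7", "Rid7"), "differ")
})
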