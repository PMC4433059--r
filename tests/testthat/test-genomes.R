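test_that("single-linkage MOTU grouping follows transitive closure", {
  d <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d) <- 0
  # all distances above the cutoff: singletons
  expect_length(motu_cluster(d, 0.03), 3L)
  # all below: one group
  d2 <- d * 0.01
  g2 <- motu_cluster(d2, 0.03)
  expect_length(g2, 1L)
  expect_equal(g2[[1]]$members, c("a", "b", "c"))
  # transitivity: a-b and b-c close, a-c not, still one group
  d3 <- matrix(c(0, 0.02, 0.05, 0.02, 0, 0.02, 0.05, 0.02, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  g3 <- motu_cluster(d3, 0.03)
  expect_length(g3, 1L)
  expect_equal(g3[[1]]$members, c("a", "b", "c"))
  # validation
  d_bad <- d3
  d_bad[1, 2] <- 0.9
  expect_error(motu_cluster(d_bad, 0.03), "asymmetric")
  expect_error(motu_cluster(d3, 1.5), "cutoff")
})

test_that("MOTU groups equal the brute-force closure on random matrices", {
  set.seed(17)
  for (k in 1:15) {
    n <- sample(2:20, 1)
    d <- random_distance_matrix(n)
    cutoff <- stats::runif(1, 0.2, 0.8)
    got <- lapply(motu_cluster(d, cutoff), `[[`, "members")
    want <- oracle_components(d, cutoff)
    expect_equal(got, want)
    # partition: disjoint and exhaustive
    all_members <- unlist(got)
    expect_equal(sort(all_members), sort(rownames(d)))
  }
})

test_that("representative selection maximizes interest with stable ties", {
  recs <- data.frame(genome_id = c("a", "b", "c"),
                     interest_score = c(3, 7, 5))
  expect_equal(select_representative(list(members = c("a", "b")), recs), "b")
  recs2 <- data.frame(genome_id = c("a", "b"), interest_score = c(5, 5))
  expect_equal(select_representative(list(members = c("b", "a")), recs2), "a")
  expect_equal(select_representative(list(members = "c"), recs), "c")
  expect_error(select_representative(list(members = c("a", "zz")), recs), "zz")
  # permutation invariance via the dereplication wrapper
  d <- random_distance_matrix(6)
  recs3 <- data.frame(genome_id = rownames(d),
                      interest_score = c(1, 9, 2, 9, 5, 3))
  der <- motu_dereplicate(d, recs3, 0.5)
  der2 <- motu_dereplicate(d[6:1, 6:1], recs3[6:1, ], 0.5)
  expect_equal(der$representative, der2$representative)
})

test_that("copy-number table tallies classified proteins per genome", {
  recs <- data.frame(genome_id = c("g1", "g2"), size_bp = c(4e6, 5e6),
                     taxon_domain = "bacteria")
  cls <- data.frame(protein_id = paste0("p", 1:4),
                    genome_id = c("g1", "g1", "g1", "g2"),
                    subfamily = c("RidA", "Rid2", "Rid2", "UNCLASSIFIED"),
                    score = 100, margin = 10, arg_site_residue = "R",
                    competent = TRUE, atypical = FALSE,
                    fusion_count = c(3L, 1L, 1L, 0L))
  tab <- copy_number_table(cls, recs)
  expect_equal(tab$RidA[tab$genome_id == "g1"], 1L)
  expect_equal(tab$Rid2[tab$genome_id == "g1"], 2L)
  expect_equal(tab$total, c(3, 0))  # UNCLASSIFIED excluded, g2 all-zero
  # totals equal the number of classified records
  expect_equal(sum(tab$total), sum(cls$subfamily != "UNCLASSIFIED"))
  # fusion proteins count once per protein, or per domain on request
  tab_dom <- copy_number_table(cls, recs, count_mode = "domains")
  expect_equal(tab_dom$RidA[tab_dom$genome_id == "g1"], 3L)
  # empty classifications give an all-zero table over the records
  tab0 <- copy_number_table(cls[0, ], recs)
  expect_true(all(tab0$total == 0))
  expect_equal(nrow(tab0), 2L)
})

test_that("size correlation is Pearson product-moment with guard rails", {
  mk_tab <- function(size, total) {
    data.frame(genome_id = paste0("g", seq_along(size)),
               size_bp = size, total = total)
  }
  # perfect linearity
  expect_equal(size_correlation(mk_tab(1:10 * 1e6, 1:10))$r, 1)
  # hand-evaluated Pearson on the five fixed pairs
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 3, 2, 4)
  n <- 5
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  got <- size_correlation(mk_tab(x, y))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$n, 5L)
  # affine rescaling with positive slope leaves r unchanged; bounds hold
  got2 <- size_correlation(mk_tab(3 * x + 7, y))
  expect_equal(got2$r, r_hand, tolerance = 1e-12)
  expect_true(abs(got$r) <= 1)
  # degenerate inputs are missing with a reason, not numbers
  tiny <- size_correlation(mk_tab(c(1, 2), c(1, 2)))
  expect_true(is.na(tiny$r))
  const <- size_correlation(mk_tab(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(const$r))
  expect_equal(attr(const$r, "reason"), "constant variable")
  # eukaryotes excluded when domain labels are present
  tab <- mk_tab(c(1, 2, 3, 100), c(1, 2, 3, 1))
  tab$taxon_domain <- c("bacteria", "bacteria", "archaea", "eukaryote")
  expect_equal(size_correlation(tab)$n, 3L)
  expect_equal(size_correlation(tab)$r, 1)
})

test_that("iTOL export follows leaf order, reports unmatched, round-trips", {
  recs <- data.frame(genome_id = c("a", "b", "zz"), size_bp = c(1e6, 2e6, 3e6))
  cls <- data.frame(protein_id = "p1", genome_id = "b", subfamily = "RidA",
                    score = 1, margin = 1, arg_site_residue = "R",
                    competent = TRUE, atypical = FALSE, fusion_count = 1L)
  tab <- copy_number_table(cls, recs)
  exp <- export_itol(tab, "(b,a);")
  # two data lines, tree leaf order b then a
  body <- exp$lines[!startsWith(exp$lines, "#")]
  expect_length(body, 2L)
  expect_equal(sub("\t.*", "", body), c("b", "a"))
  expect_equal(exp$unmatched, "zz")
  back <- parse_itol(exp$lines)
  expect_equal(back$RidA, tab$RidA[match(back$genome_id, tab$genome_id)])
  expect_equal(back$size_bp, tab$size_bp[match(back$genome_id, tab$genome_id)])
  expect_error(export_itol(tab, "((a,b;"), "malformed newick")
})
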