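test_that("PSSM column scores match the hand-evaluated log-odds formula", {
  # column {A,A,A,C}, uniform background, beta = 1
  aln <- new_alignment("c1", c(a = "A", b = "A", c = "A", d = "C"))
  p <- build_profile(aln, "test")
  expect_equal(unname(p$scores[1, "A"]), log2((3 + 1 / 20) / (4 + 1) / (1 / 20)),
               tolerance = 1e-12)
  expect_equal(unname(p$scores[1, "A"]), 3.609, tolerance = 1e-3)
  expect_equal(unname(p$scores[1, "C"]), log2((1.05 / 5) / 0.05), tolerance = 1e-12)

  # invariant column of 5 x R
  aln2 <- new_alignment("c2", c(a = "R", b = "R", c = "R", d = "R", e = "R"))
  p2 <- build_profile(aln2, "test")
  expect_equal(unname(p2$scores[1, "R"]), log2((5.05 / 6) / 0.05), tolerance = 1e-12)
  expect_equal(unname(p2$scores[1, "R"]), 4.073, tolerance = 1e-3)

  # background-proportional counts with beta -> 0+ give score ~ 0
  col <- paste(rep(aa_alphabet(), 2), collapse = "")
  rows <- strsplit(col, "")[[1L]]
  aln3 <- new_alignment("c3", stats::setNames(rows, paste0("s", seq_along(rows))))
  p3 <- build_profile(aln3, "test", pseudocount_mass = 1e-9)
  expect_true(all(abs(p3$scores) < 1e-8))
})

test_that("smoothed frequencies are normalized and scores honor invariants", {
  set.seed(31)
  rows <- replicate(12, paste(sample(aa_alphabet(), 25, replace = TRUE),
                              collapse = ""))
  aln <- new_alignment("rand", stats::setNames(rows, paste0("s", 1:12)))
  p <- build_profile(aln, "rand", pseudocount_mass = 2.5)
  # smoothed frequencies (n + beta q) / (N + beta) recovered from scores
  smoothed <- 2^p$scores * rep(p$background, each = p$length)
  expect_true(all(abs(rowSums(smoothed) - 1) < 1e-9))
  # row-order invariance
  perm <- sample(length(rows))
  p_perm <- build_profile(new_alignment("rand", stats::setNames(
    rows[perm], paste0("s", 1:12)[perm])), "rand", pseudocount_mass = 2.5)
  expect_equal(unname(p$scores), unname(p_perm$scores))
  # the consensus attains the per-column maximum everywhere
  cons <- strsplit(profile_consensus(p), "")[[1L]]
  for (j in seq_len(p$length)) {
    expect_equal(unname(p$scores[j, cons[j]]), max(p$scores[j, ]))
  }
})

test_that("gap-heavy columns are trimmed and key sites in them are refused", {
  aln <- new_alignment("g", c(a = "A-CD", b = "A-CD", c = "AAC-", d = "A--D"))
  # col2 has 3/4 gaps (trimmed); col4 has 1/4 (kept)
  p <- build_profile(aln, "g")
  expect_equal(p$length, 3L)
  expect_equal(p$kept_columns, c(1L, 3L, 4L))
  expect_error(
    build_profile(aln, "g", key_sites = c(tyr = 1, arg = 2, glu = 4)),
    "trimmed")
  # remapping: original column 4 becomes trimmed column 3
  p2 <- build_profile(aln, "g", key_sites = c(tyr = 1, arg = 3, glu = 4))
  expect_equal(unname(p2$key_sites), c(1L, 2L, 3L))
  expect_error(build_profile(aln, "g", pseudocount_mass = 0), "> 0")
  all_gap <- new_alignment("ag", c(a = "--", b = "--"))
  expect_error(build_profile(all_gap, "ag"), "degenerate")
})

test_that("conservation logo matches closed-form information content", {
  # invariant column: log2(20) bits; uniform over all 20: 0 bits;
  # half A / half C: log2(20) - 1
  inv <- new_alignment("i", c(a = "R", b = "R", c = "R"))
  expect_equal(conservation_logo(inv)$information_bits, log2(20))
  uni <- new_alignment("u", stats::setNames(aa_alphabet(),
                                            paste0("s", 1:20)))
  expect_equal(conservation_logo(uni)$information_bits, 0)
  half <- new_alignment("h", c(a = "A", b = "A", c = "C", d = "C"))
  expect_equal(conservation_logo(half)$information_bits, log2(20) - 1)
  # all-gap column flagged with 0 bits
  gap <- new_alignment("g", c(a = "A-", b = "C-"))
  lg <- conservation_logo(gap)
  expect_true(lg$all_gap[2])
  expect_equal(lg$information_bits[2], 0)
  # bounds and entropy monotonicity on random columns
  set.seed(7)
  for (k in 1:20) {
    rows <- sample(aa_alphabet(), 30, replace = TRUE)
    a <- new_alignment("r", stats::setNames(rows, paste0("s", 1:30)))
    lr <- conservation_logo(a)
    expect_true(lr$information_bits >= 0 && lr$information_bits <= log2(20))
  }
})

test_that("footprint consensus ranks arg-site residues and breaks ties", {
  # 90% R / 10% S at the arg site mirrors the RidA serine minority
  rows <- c(rep("YRE", 9), "YSE")
  aln <- new_alignment("ra", stats::setNames(rows, paste0("s", 1:10)))
  fp <- data.frame(index = 1:3, start = 1:3, end = 1:3)
  p <- build_profile(aln, "RidA", footprints = fp,
                     key_sites = c(tyr = 1, arg = 2, glu = 3))
  fc <- footprint_consensus(p)
  expect_equal(unname(fc$arg_site), c(0.9, 0.1))
  expect_equal(names(fc$arg_site), c("R", "S"))
  # invariant W (Rid4-like)
  rows4 <- rep("YWE", 5)
  p4 <- build_profile(new_alignment("r4", stats::setNames(rows4, paste0("s", 1:5))),
                      "Rid4", footprints = fp,
                      key_sites = c(tyr = 1, arg = 2, glu = 3))
  fc4 <- footprint_consensus(p4)
  expect_equal(names(fc4$arg_site)[1], "W")
  # 50/50 tie -> lexicographically smallest, flagged
  tie <- new_alignment("t", c(a = "A", b = "C"))
  pt <- build_profile(tie, "t", footprints = data.frame(index = 1, start = 1, end = 1),
                      key_sites = c(tyr = 1, arg = 1, glu = 1))
  ft <- footprint_consensus(pt)
  expect_equal(ft$regions$consensus[1], "A")
  expect_true(ft$regions$tie[1])
})

test_that("profiles serialize and round-trip through JSON", {
  sw <- small_world()
  p <- sw$profiles$RidA
  path <- withr::local_tempfile(fileext = ".json")
  write_profile(p, path)
  p2 <- read_profile(path)
  expect_equal(p2$scores, p$scores)
  expect_equal(p2$key_sites, p$key_sites)
  expect_equal(p2$footprints$start, p$footprints$start)
  expect_equal(p2$subfamily, "RidA")
})

test_that("logo TSV export carries frequency-scaled letter heights", {
  aln <- toy_alignment()
  lg <- conservation_logo(aln)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_logo_tsv(lg, path)
  back <- read_tsv_strict(path)
  expect_equal(nrow(back), nrow(df))
  c1 <- back[back$column == 1, ]
  expect_equal(sum(c1$frequency), 1)
  expect_equal(c1$bits, c1$frequency * lg$information_bits[1])
})
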