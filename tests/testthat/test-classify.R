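test_that("E-value follows the Karlin-Altschul formula and its contract", {
  # worked example: m = n = 130, S = 50 -> E ~ 1.1e-3, above the 1e-4 cutoff
  e <- karlin_evalue(50, 130, 130)
  expect_equal(e, 0.041 * 130 * 130 * exp(-0.267 * 50), tolerance = 1e-12)
  expect_equal(e, 1.1e-3, tolerance = 0.02)
  expect_gt(e, 1e-4)
  # strictly decreasing in score
  scores <- seq(10, 200, by = 5)
  es <- karlin_evalue(scores, 130, 130)
  expect_true(all(diff(es) < 0))
})

test_that("candidate search seeds on shared k-mers and filters by E-value", {
  sw <- small_world()
  cons <- vapply(sw$profiles, profile_consensus, character(1))
  q <- cons["RidA"]
  names(q) <- "q_RidA"
  # identical 130-aa target passes the 1e-4 cutoff
  hits <- find_candidates(q, c(t1 = unname(q)))
  expect_equal(nrow(hits), 1L)
  expect_lte(hits$evalue, 1e-4)
  # no shared k-mer, no hit (poly-A target has no seed against the query)
  none <- find_candidates(c(qa = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
                          c(t1 = strrep("A", 50)))
  expect_equal(nrow(none), 0L)
  # empty proteome is an empty result, not an error
  expect_equal(nrow(find_candidates(q, character(0))), 0L)
  expect_error(find_candidates(q, c(t = unname(q)), kmer_k = 2), ">= 3")
})

test_that("profile scanning equals exhaustive enumeration and self-consensus wins", {
  sw <- small_world()
  profs <- sw$profiles
  # the profile's own consensus scores maximally at offset 1
  cons <- profile_consensus(profs$RidA)
  hit <- scan_subfamilies(c(p1 = cons), profs)$RidA
  expect_equal(hit$offset, 1L)
  expect_equal(hit$total_score, profile_max_score(profs$RidA), tolerance = 1e-9)
  # protein of exactly profile length has a single candidate offset
  expect_equal(scan_subfamilies(c(p2 = cons), profs)$Rid3$offset, 1L)
  # random proteins: op output equals the brute-force all-offset oracle
  set.seed(55)
  for (k in 1:12) {
    n <- sample(130:300, 1)
    seq <- paste(sample(c(aa_alphabet(), "X"), n, replace = TRUE,
                        prob = c(rep(1, 20), 0.4)), collapse = "")
    hits <- scan_subfamilies(c(p = seq), profs)
    for (fam in names(hits)) {
      oracle <- oracle_best_window(seq, profs[[fam]])
      expect_equal(hits[[fam]]$offset, oracle$offset)
      expect_equal(hits[[fam]]$total_score, oracle$score, tolerance = 1e-9)
    }
  }
  # proteins shorter than every profile yield an empty warning result
  expect_warning(h <- scan_subfamilies(c(p = "MKT"), profs), "shorter")
  expect_length(h, 0L)
})

test_that("subfamily assignment applies threshold, margin and tie rules", {
  mk <- function(fam, score) {
    structure(list(protein_id = "p", subfamily = fam, offset = 1L,
                   total_score = score, region_scores = NULL,
                   key_residues = c(tyr = "Y", arg = "R", glu = "E")),
              class = "rid_domain_hit")
  }
  hits <- c(list(RidA = mk("RidA", 100)),
            stats::setNames(lapply(paste0("Rid", 1:7), mk, score = 50),
                            paste0("Rid", 1:7)))
  r <- assign_subfamily(hits, score_threshold = 60)
  expect_equal(r$assigned, "RidA")
  expect_equal(r$margin, 50)
  expect_true(r$hydrolase_competent)
  # all below threshold -> UNCLASSIFIED
  r2 <- assign_subfamily(hits, score_threshold = 200)
  expect_equal(r2$assigned, "UNCLASSIFIED")
  # exact tie RidA = Rid2 -> RidA by fixed order, tie recorded
  hits3 <- list(Rid2 = mk("Rid2", 80), RidA = mk("RidA", 80))
  r3 <- assign_subfamily(hits3, score_threshold = 10)
  expect_equal(r3$assigned, "RidA")
  expect_true(r3$tie)
  # empty hit set
  r4 <- assign_subfamily(list(), score_threshold = 10)
  expect_equal(r4$assigned, "UNCLASSIFIED")
  expect_equal(r4$best_score, 0)
  # determinism under iteration order
  r5 <- assign_subfamily(rev(hits), score_threshold = 60)
  expect_equal(r5$assigned, r$assigned)
  expect_equal(r5$margin, r$margin)
})

test_that("active-site calls read the catalytic residues through the offset", {
  sw <- small_world()
  profs <- sw$profiles
  arg_col <- profs$RidA$key_sites[["arg"]]
  # Rid4 consensus carries the tryptophan replacement: not competent
  cons4 <- profile_consensus(profs$Rid4)
  hit4 <- scan_subfamilies(c(p = cons4), profs)$Rid4
  call4 <- call_active_site(cons4, hit4)
  expect_equal(call4$arg_site_residue, "W")
  expect_false(call4$hydrolase_competent)
  # RidA consensus: arginine, hydrolase-competent
  consA <- profile_consensus(profs$RidA)
  hitA <- scan_subfamilies(c(p = consA), profs)$RidA
  callA <- call_active_site(consA, hitA)
  expect_equal(callA$arg_site_residue, "R")
  expect_true(callA$hydrolase_competent)
  # serine variant: not competent but flagged atypical within RidA
  varS <- consA
  substr(varS, arg_col, arg_col) <- "S"
  hitS <- scan_subfamilies(c(p = varS), profs)$RidA
  callS <- call_active_site(varS, hitS)
  expect_equal(callS$arg_site_residue, "S")
  expect_false(callS$hydrolase_competent)
  expect_true(callS$atypical_serine)
  # truncated ORF: key site beyond the protein reports missing/unknown
  trunc <- substr(consA, 1, arg_col - 5)
  fake_hit <- hitA
  fake_hit$key_residues[["arg"]] <- NA_character_
  callT <- call_active_site(trunc, fake_hit)
  expect_true(is.na(callT$arg_site_residue))
  expect_true(is.na(callT$hydrolase_competent))
})

test_that("fusion detection selects non-overlapping domains like brute force", {
  sw <- small_world()
  profs <- sw$profiles
  thr <- default_score_thresholds(profs)
  consA <- profile_consensus(profs$RidA)
  # three RidA domains with 5-aa linkers: the planted 3x arrangement
  p3 <- paste(c(consA, consA, consA), collapse = "GGGGS")
  f3 <- detect_fusion(c(p = p3), profs, thr)
  expect_equal(f3$domain_count, 3L)
  expect_true(f3$is_3x)
  expect_true(all(diff(f3$intervals$start) > profs$RidA$length))
  # single domain
  f1 <- detect_fusion(c(p = consA), profs, thr)
  expect_equal(f1$domain_count, 1L)
  expect_false(f1$is_3x)
  # two domains, 10-aa linker: equals the brute-force maximal selection
  p2 <- paste(c(consA, consA), collapse = "GGGGSGGGGS")
  f2 <- detect_fusion(c(p = p2), list(profs$RidA), thr["RidA"])
  oracle <- oracle_best_pair(p2, profs$RidA, thr[["RidA"]])
  expect_equal(f2$domain_count, 2L)
  expect_equal(f2$intervals$start, oracle$starts)
  expect_equal(sum(f2$intervals$score), oracle$total, tolerance = 1e-9)
  # nothing above threshold
  f0 <- detect_fusion(c(p = strrep("A", 200)), profs, thr)
  expect_equal(f0$domain_count, 0L)
  expect_true(f0$not_rid)
})

test_that("the two-stage filter leaves profile-incoherent candidates unclassified", {
  sw <- small_world()
  profs <- sw$profiles
  consA <- profile_consensus(profs$RidA)
  # a protein sharing an exact 60-residue block with the query passes the
  # relaxed E-value search, but its best profile window stays far below
  # the classification threshold
  set.seed(77)
  scramble <- paste(sample(strsplit(paste0(consA, consA), "")[[1L]]),
                    collapse = "")
  chimera <- paste0(substr(scramble, 1, 100), substr(consA, 30, 89),
                    substr(scramble, 101, 200))
  hits <- find_candidates(c(q = consA), c(t = chimera))
  expect_equal(nrow(hits), 1L)
  expect_lte(hits$evalue, 1e-4)
  cls <- classify_proteome(c(`g1|t` = chimera), profs)
  expect_equal(cls$subfamily, "UNCLASSIFIED")
})
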