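#' Configuration of a synthetic Rid genome world
#'
#' Defines the study conditions the generator emulates: eight ~130-aa Rid
#' subfamilies with footprint residues (R vs W vs variable at the catalytic
#' arginine site, ~10% Ser within RidA), rare 3x tandem fusions, partner
#' genes planted near Rid genes at controlled per-role clustering
#' probabilities, and a positive genome-size/Rid-copy-number correlation.
#'
#' @param seed Integer RNG seed; every random choice in the world derives
#'   from it.
#' @param n_genomes Number of genomes (default 200).
#' @param domain_length Rid domain length in residues (default 130).
#' @param subfamily_prevalence Named per-subfamily weights used to assign
#'   each planted Rid copy a subfamily (RidA-heavy by default, emulating
#'   RidA ubiquity).
#' @param serine_fraction Fraction of RidA instances carrying S instead of
#'   R at the arg site (default 0.10).
#' @param fusion_prob Probability a RidA gene is a 3x tandem fusion
#'   (default 0.02).
#' @param role_cluster_prob Named per-partner-role probability that a
#'   genome carrying at least one Rid gene has that role planted within
#'   the cluster window (<= 3 intervening genes, <= 5 kb).
#' @param target_rho Desired Pearson correlation between genome size and
#'   Rid copy number (default 0.69).
#' @param divergence Per-column substitution probability away from the
#'   subfamily consensus (default 0.05). Values >= 0.5 trigger a warning:
#'   subfamilies may become inseparable.
#' @param indel_rate Per-column deletion probability in sampled proteins
#'   (default 0; profile scanning is gapless, so indels degrade recovery).
#' @param n_rows Alignment rows per subfamily seed alignment (default 50).
#' @param n_decoys Shuffled-composition decoy proteins per genome
#'   (default 3).
#' @param mean_copies Mean Rid copy number per genome (default 4).
#' @param rid7_companion_prob Probability that a Rid7 gene participating in
#'   a cluster gets a companion RidA gene planted in the same cluster
#'   (default 0.75, emulating the observation that most Rid7 clusters also
#'   contain RidA).
#' @param archaea_fraction Fraction of genomes labeled archaea
#'   (default 0.055).
#' @param size_a,size_b,size_sd Genome-size model parameters:
#'   size_bp = round(size_a + size_b * z + Normal(0, size_sd)) with z the
#'   shared latent variable that also drives copy number.
#' @param n_contigs 1 (default) or 2; with 2, the distant background block
#'   is emitted on a second contig for contig-boundary tests.
#' @return A validated `rid_world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_genomes = 200L,
                         domain_length = 130L,
                         subfamily_prevalence = c(
                           RidA = 0.90, Rid1 = 0.20, Rid2 = 0.30,
                           Rid3 = 0.20, Rid4 = 0.15, Rid5 = 0.10,
                           Rid6 = 0.10, Rid7 = 0.25),
                         serine_fraction = 0.10,
                         fusion_prob = 0.02,
                         role_cluster_prob = c(
                           THREONINE_DEHYDRATASE = 0.50,
                           ASPARTATE_AMINOTRANSFERASE = 0.25,
                           CYSTEINE_DESULFURASE = 0.25,
                           AMINE_OXIDASE = 0.30,
                           ACT = 0.30, OCT = 0.20, CPS = 0.15, CK = 0.10),
                         target_rho = 0.69,
                         divergence = 0.05,
                         indel_rate = 0,
                         n_rows = 50L,
                         n_decoys = 3L,
                         mean_copies = 4,
                         rid7_companion_prob = 0.75,
                         archaea_fraction = 0.055,
                         size_a = 4e6, size_b = 1e6, size_sd = 2.5e5,
                         n_contigs = 1L) {
  probs <- c(subfamily_prevalence, serine_fraction, fusion_prob,
             role_cluster_prob, divergence, indel_rate,
             rid7_companion_prob, archaea_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(target_rho) > 1) stop("target_rho must lie in [-1, 1]")
  if (n_genomes < 3L) stop("n_genomes must be >= 3")
  if (domain_length < 20L) stop("domain_length must be >= 20")
  if (!setequal(names(subfamily_prevalence), rid_subfamilies())) {
    stop("subfamily_prevalence must name all eight subfamilies")
  }
  if (divergence >= 0.5) {
    warning("divergence >= 0.5: subfamilies may become inseparable")
  }
  structure(
    list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
         domain_length = as.integer(domain_length),
         subfamily_prevalence = subfamily_prevalence[rid_subfamilies()],
         serine_fraction = serine_fraction, fusion_prob = fusion_prob,
         role_cluster_prob = role_cluster_prob, target_rho = target_rho,
         divergence = divergence, indel_rate = indel_rate,
         n_rows = as.integer(n_rows), n_decoys = as.integer(n_decoys),
         mean_copies = mean_copies,
         rid7_companion_prob = rid7_companion_prob,
         archaea_fraction = archaea_fraction,
         size_a = size_a, size_b = size_b, size_sd = size_sd,
         n_contigs = as.integer(n_contigs)),
    class = "rid_world_config")
}

# footprint regions and key sites for a domain of length L, scaled from the
# 130-column template (TdcF-numbering homologs tyr 17, arg 105, glu 120)
world_footprints <- function(L) {
  scale_pos <- function(p) pmax(1L, pmin(L, as.integer(round(p * L / 130))))
  fp <- data.frame(index = 1:6,
                   start = scale_pos(c(11, 30, 52, 72, 98, 116)),
                   end = scale_pos(c(22, 40, 62, 82, 110, 126)))
  ks <- c(tyr = scale_pos(17), arg = scale_pos(105), glu = scale_pos(120))
  list(footprints = fp, key_sites = ks)
}

# key-residue generation rules per subfamily: arg site R (RidA with ~10% S;
# Rid1-3), W (Rid4, Rid7), variable (Rid5, Rid6); glu site E everywhere;
# tyr site Y except Rid3 (I) and Rid2 (variable)
draw_key_residues <- function(subfamily, serine_fraction, arg_override = NULL) {
  alpha <- aa_alphabet()
  arg <- if (!is.null(arg_override)) arg_override else switch(
    subfamily,
    RidA = if (stats::runif(1) < serine_fraction) "S" else "R",
    Rid1 = , Rid2 = , Rid3 = "R",
    Rid4 = , Rid7 = "W",
    Rid5 = , Rid6 = sample(alpha, 1L))
  tyr <- switch(subfamily,
                Rid3 = "I",
                Rid2 = sample(alpha, 1L),
                "Y")
  c(tyr = tyr, arg = arg, glu = "E")
}

# sample one domain sequence: subfamily consensus mutated per column with
# probability `divergence`, key sites drawn by rule (exempt from divergence
# so the planted truth residue is the emitted residue)
sample_domain <- function(consensus_chars, subfamily, cfg, key_sites,
                          arg_override = NULL) {
  alpha <- aa_alphabet()
  L <- length(consensus_chars)
  chars <- consensus_chars
  mut <- which(stats::runif(L) < cfg$divergence)
  mut <- setdiff(mut, key_sites)
  for (i in mut) {
    chars[i] <- sample(setdiff(alpha, chars[i]), 1L)
  }
  kr <- draw_key_residues(subfamily, cfg$serine_fraction, arg_override)
  chars[key_sites[["tyr"]]] <- kr[["tyr"]]
  chars[key_sites[["arg"]]] <- kr[["arg"]]
  chars[key_sites[["glu"]]] <- kr[["glu"]]
  if (cfg$indel_rate > 0) {
    del <- which(stats::runif(L) < cfg$indel_rate)
    del <- setdiff(del, key_sites)
    if (length(del)) chars <- chars[-del]
  }
  list(seq = paste(chars, collapse = ""), key_residues = kr)
}

#' Generate the eight subfamily seed alignments and consensus sequences
#'
#' Eight consensus sequences share a common family core (each non-key
#' column mutated away from the core with probability 0.5, so subfamilies
#' are related but separable) and six fixed footprint regions. Key sites
#' follow the family conservation pattern: arg site R in RidA and Rid1-3
#' (RidA rows carry S at `serine_fraction`), W in Rid4 and Rid7, variable
#' in Rid5 and Rid6; glu site E in all; tyr site Y except Rid3 (I) and
#' Rid2 (variable). `n_rows` alignment rows per subfamily are sampled at
#' the configured divergence. Consumes the current RNG stream; callers
#' seed it (see [generate_world()]).
#'
#' @param config A [world_config()].
#' @return List: `alignments` (named list of [rid_alignment][new_alignment]),
#'   `consensus` (named character), `footprints`, `key_sites`.
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "rid_world_config"))
  alpha <- aa_alphabet()
  L <- config$domain_length
  geom <- world_footprints(L)
  ks <- geom$key_sites
  core <- sample(alpha, L, replace = TRUE)
  fams <- rid_subfamilies()
  consensus <- list()
  alignments <- list()
  for (fam in fams) {
    cons <- core
    flip <- which(stats::runif(L) < 0.5)
    flip <- setdiff(flip, ks)
    for (i in flip) cons[i] <- sample(setdiff(alpha, cons[i]), 1L)
    # consensus-level key residues (row-level variability drawn per row)
    cons[ks[["glu"]]] <- "E"
    cons[ks[["tyr"]]] <- switch(fam, Rid3 = "I", Rid2 = sample(alpha, 1L), "Y")
    cons[ks[["arg"]]] <- switch(fam, RidA = , Rid1 = , Rid2 = , Rid3 = "R",
                                Rid4 = , Rid7 = "W", sample(alpha, 1L))
    rows <- character(config$n_rows)
    row_cfg <- config
    row_cfg$indel_rate <- 0  # seed alignments are gapless
    for (i in seq_len(config$n_rows)) {
      rows[i] <- sample_domain(cons, fam, row_cfg, ks)$seq
    }
    names(rows) <- sprintf("%s_seed%02d", fam, seq_len(config$n_rows))
    alignments[[fam]] <- new_alignment(fam, rows)
    consensus[[fam]] <- paste(cons, collapse = "")
  }
  list(alignments = alignments, consensus = unlist(consensus),
       footprints = geom$footprints, key_sites = ks)
}

# deterministic calibration of the latent-variable copy link: solve the
# closed-form moment equation for d in
#   copies ~ Poisson(exp(log(m) - d^2/2 + d z)),  size = a + b z + noise
# whose exact correlation is
#   rho(d) = [m d / sqrt(m + m^2 (e^{d^2} - 1))] * b / sqrt(b^2 + sd^2)
calibrate_copy_link <- function(target_rho, mean_copies, size_b, size_sd) {
  if (target_rho <= 0) return(0)
  m <- mean_copies
  size_factor <- size_b / sqrt(size_b^2 + size_sd^2)
  rho_of <- function(d) {
    m * d / sqrt(m + m^2 * (exp(d^2) - 1)) * size_factor
  }
  upper <- 0.8  # rho_of is increasing on [0, 0.8] for m >= 2
  if (target_rho >= rho_of(upper)) {
    stop("target_rho ", target_rho, " exceeds the attainable maximum ",
         round(rho_of(upper), 3), " for this size-noise setting")
  }
  stats::uniroot(function(d) rho_of(d) - target_rho, c(0, upper),
                 tol = 1e-10)$root
}

# ---- genome layout ------------------------------------------------------
# Each Rid copy gets a block: the rid gene in the middle, planted partner
# (and companion RidA) genes on alternating sides with at most
# `bg` + position - 1 <= 3 genes between a partner and the rid gene, and
# block-internal gaps of 50-150 bp, so every planted pair satisfies the
# default cluster window (<= 3 intervening, <= 5 kb) by construction.
# Blocks are separated by 5 background genes with 2 kb gaps, so no
# cross-block pair can satisfy it.

new_block <- function(center) {
  list(center = center, left = list(), right = list(),
       left_bg = 0L, right_bg = 0L)
}

# try to add a satellite gene spec to a block; the new gene's intervening
# count relative to the block center equals the entries already on its
# side, so a side accepts a gene only while it holds <= 3 entries.
# Returns the updated block, or NULL if both sides are full.
block_add <- function(block, spec) {
  sides <- if (length(block$right) <= length(block$left)) {
    c("right", "left")
  } else {
    c("left", "right")
  }
  for (s in sides) {
    if (length(block[[s]]) == 0L) {
      # pad the first placement on a side with 0-2 background genes
      nb <- sample(0:2, 1L)
      block[[s]] <- lapply(seq_len(nb), function(k) {
        list(role = "OTHER", len = sample(300:600, 1L),
             gene_id = NA_character_)
      })
      block[[paste0(s, "_bg")]] <- nb
    }
    if (length(block[[s]]) <= 3L) {
      block[[s]] <- c(block[[s]], list(spec))
      return(block)
    }
  }
  NULL
}

# flatten a block into an ordered list of gene specs
block_genes <- function(block) {
  c(rev(block$left), list(block$center), block$right)
}

#' Generate a fully labeled synthetic genome world
#'
#' Per genome: a latent standard-normal z drives both genome size
#' (size_a + size_b z + noise) and the Rid copy count
#' (Poisson with log-mean calibrated so that corr(size, copies) matches
#' `target_rho`); each copy is assigned a subfamily by prevalence weights
#' and its protein sampled from the subfamily consensus at the configured
#' divergence; RidA copies become 3x tandem fusions (three domains joined
#' by 5-aa GGGGS linkers) with probability `fusion_prob`; for each partner
#' role, a genome with Rid genes gets a partner gene planted inside the
#' cluster window of a random Rid copy with the role's probability;
#' shuffled-composition decoy proteins are added for false-positive
#' testing; distant partner-role genes (outside any cluster window) keep
#' the clustering statistics honest. All randomness derives from the
#' config seed; regenerating with the same config is identical.
#'
#' @param config A [world_config()].
#' @return Object of class `rid_world`: config, profiles (alignments,
#'   consensus, footprints, key_sites), genomes (data frame), features
#'   (data frame), proteome (data frame: protein_id, genome_id, sequence),
#'   truth (proteins, copy_numbers, planted, calibration).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "rid_world_config"))
  set.seed(config$seed)
  cfg <- config
  prof <- generate_profiles(cfg)
  L <- cfg$domain_length
  geom <- world_footprints(L)
  ks <- geom$key_sites
  cons_chars <- lapply(prof$consensus, function(s) strsplit(s, "")[[1L]])
  d_link <- calibrate_copy_link(cfg$target_rho, cfg$mean_copies,
                                cfg$size_b, cfg$size_sd)
  c_link <- log(cfg$mean_copies) - d_link^2 / 2
  prev <- cfg$subfamily_prevalence / sum(cfg$subfamily_prevalence)
  fams <- rid_subfamilies()
  roles <- names(cfg$role_cluster_prob)

  genomes <- vector("list", cfg$n_genomes)
  features <- vector("list", cfg$n_genomes)
  proteins <- vector("list", cfg$n_genomes)
  truth_prot <- vector("list", cfg$n_genomes)
  truth_plant <- vector("list", cfg$n_genomes)

  for (g in seq_len(cfg$n_genomes)) {
    gid <- sprintf("g%04d", g)
    z <- stats::rnorm(1)
    size_model <- round(cfg$size_a + cfg$size_b * z +
                          stats::rnorm(1, 0, cfg$size_sd))
    n_copies <- stats::rpois(1, exp(c_link + d_link * z))
    copy_fams <- if (n_copies > 0) {
      sample(fams, n_copies, replace = TRUE, prob = prev)
    } else character(0)

    # --- rid copies and their proteins
    copies <- list()
    for (i in seq_along(copy_fams)) {
      fam <- copy_fams[[i]]
      fused <- fam == "RidA" && stats::runif(1) < cfg$fusion_prob
      if (fused) {
        arg <- if (stats::runif(1) < cfg$serine_fraction) "S" else "R"
        doms <- lapply(1:3, function(k) {
          sample_domain(cons_chars[[fam]], fam, cfg, ks, arg_override = arg)
        })
        seq <- paste(vapply(doms, `[[`, character(1), "seq"),
                     collapse = "GGGGS")
        kr <- doms[[1L]]$key_residues
        n_dom <- 3L
      } else {
        dom <- sample_domain(cons_chars[[fam]], fam, cfg, ks)
        seq <- dom$seq
        kr <- dom$key_residues
        n_dom <- 1L
      }
      pid <- sprintf("%s|p%03d", gid, i)
      copies[[i]] <- list(protein_id = pid, subfamily = fam, seq = seq,
                          arg = kr[["arg"]], fusion_count = n_dom,
                          gene_id = sprintf("%s_rid%03d", gid, i))
    }

    # --- partner-role planting (per genome x role, only if rid genes exist)
    blocks <- lapply(copies, function(cp) {
      new_block(list(role = paste0("RID:", cp$subfamily),
                     len = 3L * nchar(cp$seq) + 3L, gene_id = cp$gene_id))
    })
    plant_rows <- list()
    partner_counter <- 0L
    for (r in roles) {
      eligible <- length(copies) > 0L
      planted <- eligible && stats::runif(1) < cfg$role_cluster_prob[[r]]
      rec <- list(genome_id = gid, role = r, eligible = eligible,
                  planted = FALSE, rid_gene_id = NA_character_,
                  partner_gene_id = NA_character_,
                  rid_subfamily = NA_character_)
      if (planted) {
        order_try <- sample(seq_along(copies))
        for (ci in order_try) {
          partner_counter <- partner_counter + 1L
          pgid <- sprintf("%s_par%03d", gid, partner_counter)
          nb <- block_add(blocks[[ci]],
                          list(role = r, len = sample(900:1200, 1L),
                               gene_id = pgid))
          if (!is.null(nb)) {
            blocks[[ci]] <- nb
            rec$planted <- TRUE
            rec$rid_gene_id <- copies[[ci]]$gene_id
            rec$rid_subfamily <- copies[[ci]]$subfamily
            rec$partner_gene_id <- pgid
            break
          }
        }
      }
      plant_rows[[length(plant_rows) + 1L]] <- rec
    }

    # --- companion RidA genes inside Rid7 clusters
    companions <- list()
    for (ci in seq_along(copies)) {
      if (copies[[ci]]$subfamily != "Rid7") next
      has_partner <- any(vapply(plant_rows, function(p) {
        isTRUE(p$planted) && identical(p$rid_gene_id, copies[[ci]]$gene_id)
      }, logical(1)))
      if (!has_partner) next
      if (stats::runif(1) >= cfg$rid7_companion_prob) next
      dom <- sample_domain(cons_chars[["RidA"]], "RidA", cfg, ks)
      k <- length(companions) + 1L
      pid <- sprintf("%s|pc%02d", gid, k)
      cgene <- sprintf("%s_comp%02d", gid, k)
      nb <- block_add(blocks[[ci]],
                      list(role = "RID:RidA", len = 3L * nchar(dom$seq) + 3L,
                           gene_id = cgene))
      if (is.null(nb)) next  # cluster full; companion skipped
      blocks[[ci]] <- nb
      companions[[k]] <- list(protein_id = pid, subfamily = "RidA",
                              seq = dom$seq, arg = dom$key_residues[["arg"]],
                              fusion_count = 1L, gene_id = cgene)
    }
    all_copies <- c(copies, companions)

    # --- decoys: shuffled-composition rid-like sequences
    decoys <- list()
    for (k in seq_len(cfg$n_decoys)) {
      fam <- sample(fams, 1L, prob = prev)
      dom <- sample_domain(cons_chars[[fam]], fam, cfg, ks)
      shuf <- paste(sample(strsplit(dom$seq, "")[[1L]]), collapse = "")
      decoys[[k]] <- list(protein_id = sprintf("%s|d%02d", gid, k),
                          seq = shuf,
                          gene_id = sprintf("%s_dec%02d", gid, k))
    }

    # --- distant partner-role genes (must not cluster)
    far_genes <- list()
    for (r in roles) {
      if (stats::runif(1) < 0.3) {
        far_genes[[length(far_genes) + 1L]] <-
          list(role = r, len = sample(900:1200, 1L),
               gene_id = sprintf("%s_far_%s", gid, tolower(r)))
      }
    }
    for (dec in decoys) {
      far_genes[[length(far_genes) + 1L]] <-
        list(role = "OTHER", len = 3L * nchar(dec$seq) + 3L,
             gene_id = dec$gene_id)
    }

    # --- lay out the contig(s)
    spacer <- function(i) {
      lapply(seq_len(5L), function(k) {
        list(role = "OTHER", len = sample(300:600, 1L),
             gene_id = sprintf("%s_bg%03d_%d", gid, i, k))
      })
    }
    gene_stream <- list()
    bg_i <- 0L
    for (b in blocks) {
      bg_i <- bg_i + 1L
      gene_stream <- c(gene_stream, block_genes(b), spacer(bg_i))
    }
    if (length(gene_stream) == 0L) {
      bg_i <- bg_i + 1L
      gene_stream <- spacer(bg_i)
    }
    main_ctg <- sprintf("%s_c1", gid)
    far_ctg <- if (cfg$n_contigs >= 2L) sprintf("%s_c2", gid) else main_ctg
    streams <- list()
    streams[[main_ctg]] <- gene_stream
    if (identical(far_ctg, main_ctg)) {
      streams[[main_ctg]] <- c(streams[[main_ctg]], far_genes)
    } else if (length(far_genes)) {
      streams[[far_ctg]] <- far_genes
    }
    feat_rows <- list()
    gi <- 0L
    for (ctg in names(streams)) {
      pos <- 1L
      for (spec in streams[[ctg]]) {
        gi <- gi + 1L
        id <- spec$gene_id
        if (is.null(id) || is.na(id)) id <- sprintf("%s_o%04d", gid, gi)
        big_gap <- grepl("_bg[0-9]|_far_", id)
        gap <- if (big_gap) sample(1800:2200, 1L) else sample(50:150, 1L)
        start <- pos + gap
        end <- start + spec$len - 1L
        pos <- end + 1L
        feat_rows[[gi]] <- data.frame(
          genome_id = gid, contig = ctg, gene_id = id,
          start = start, end = end,
          strand = sample(c("+", "-"), 1L), role = spec$role)
      }
    }
    feats <- do.call(rbind, feat_rows)
    extent <- max(feats$end)
    size_bp <- max(size_model, extent + 1000L, 50000L)

    genomes[[g]] <- data.frame(
      genome_id = gid,
      taxon_domain = if (stats::runif(1) < cfg$archaea_fraction) "archaea" else "bacteria",
      size_bp = size_bp,
      interest_score = round(stats::runif(1, 0, 100), 3))
    features[[g]] <- feats
    prot_list <- c(all_copies, decoys)
    proteins[[g]] <- data.frame(
      protein_id = vapply(prot_list, `[[`, character(1), "protein_id"),
      genome_id = rep(gid, length(prot_list)),
      sequence = vapply(prot_list, `[[`, character(1), "seq"))
    truth_prot[[g]] <- data.frame(
      protein_id = vapply(prot_list, `[[`, character(1), "protein_id"),
      genome_id = rep(gid, length(prot_list)),
      subfamily = c(vapply(all_copies, `[[`, character(1), "subfamily"),
                    rep("DECOY", length(decoys))),
      arg_site_residue = c(vapply(all_copies, `[[`, character(1), "arg"),
                           rep(NA_character_, length(decoys))),
      fusion_count = c(vapply(all_copies, function(x) x$fusion_count, integer(1)),
                       rep(0L, length(decoys))))
    truth_plant[[g]] <- do.call(rbind, lapply(plant_rows, as.data.frame))
  }

  genomes <- do.call(rbind, genomes)
  features <- do.call(rbind, features)
  proteome <- do.call(rbind, proteins)
  truth_proteins <- do.call(rbind, truth_prot)
  planted <- do.call(rbind, truth_plant)
  rownames(genomes) <- rownames(features) <- rownames(proteome) <-
    rownames(truth_proteins) <- rownames(planted) <- NULL

  rid_truth <- truth_proteins[truth_proteins$subfamily != "DECOY", , drop = FALSE]
  counts <- table(factor(rid_truth$genome_id, levels = genomes$genome_id),
                  factor(rid_truth$subfamily, levels = fams))
  copy_numbers <- data.frame(genome_id = genomes$genome_id,
                             as.data.frame.matrix(counts), check.names = FALSE)
  copy_numbers$total <- rowSums(counts)
  copy_numbers$size_bp <- genomes$size_bp
  copy_numbers$taxon_domain <- genomes$taxon_domain
  rownames(copy_numbers) <- NULL

  structure(
    list(config = cfg, profiles = prof, genomes = genomes,
         features = features, proteome = proteome,
         truth = list(proteins = truth_proteins,
                      copy_numbers = copy_numbers,
                      planted = planted,
                      calibration = list(d = d_link, c = c_link))),
    class = "rid_world")
}

#' @export
print.rid_world <- function(x, ...) {
  cat("rid_world: ", nrow(x$genomes), " genomes, ",
      nrow(x$features), " gene features, ",
      nrow(x$proteome), " proteins (",
      sum(x$truth$proteins$subfamily != "DECOY"), " Rid, ",
      sum(x$truth$proteins$subfamily == "DECOY"), " decoys)\n", sep = "")
  invisible(x)
}

#' Truth-summary tables of a synthetic world
#'
#' Tables in the same schemas the pipeline emits so that planted truth and
#' recovered results can be diffed directly.
#'
#' @param world A `rid_world` from [generate_world()].
#' @return List: `copy_numbers` (per-genome subfamily counts + size),
#'   `planted_proportions` (per role: eligible genomes, planted genomes,
#'   planted proportion among eligible genomes), `fusions` (registry of
#'   planted multi-domain proteins).
#' @export
world_report <- function(world) {
  stopifnot(inherits(world, "rid_world"))
  pl <- world$truth$planted
  roles <- unique(pl$role)
  planted_proportions <- do.call(rbind, lapply(roles, function(r) {
    sub <- pl[pl$role == r, , drop = FALSE]
    n_eligible <- sum(sub$eligible)
    n_planted <- sum(sub$planted)
    data.frame(role = r, n_eligible = n_eligible, n_planted = n_planted,
               proportion = if (n_eligible > 0) n_planted / n_eligible else NA_real_)
  }))
  rownames(planted_proportions) <- NULL
  tp <- world$truth$proteins
  fusions <- tp[tp$fusion_count > 1L, , drop = FALSE]
  rownames(fusions) <- NULL
  list(copy_numbers = world$truth$copy_numbers,
       planted_proportions = planted_proportions,
       fusions = fusions)
}

#' Write a synthetic world to disk as standard flat files
#'
#' Emits proteome FASTA, GFF3 feature file (plus the 7-column TSV twin),
#' per-subfamily seed alignments, genome table, truth tables, and a
#' reproducibility manifest (config + seed + package version). Output is
#' byte-identical across runs with the same config.
#'
#' @param world A `rid_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "rid_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  write_fasta(stats::setNames(world$proteome$sequence,
                              world$proteome$protein_id),
              file.path(dir, "proteins.faa"))
  write_features(world$features, file.path(dir, "features.gff3"), "gff3")
  write_features(world$features, file.path(dir, "features.tsv"), "tsv")
  write_tsv_strict(world$genomes, file.path(dir, "genomes.tsv"))
  for (fam in names(world$profiles$alignments)) {
    aln <- world$profiles$alignments[[fam]]
    write_fasta(stats::setNames(aln$seqs, aln$seq_ids),
                file.path(dir, "alignments", paste0("seed_", fam, ".fasta")))
  }
  write_tsv_strict(world$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  write_tsv_strict(world$truth$copy_numbers,
                   file.path(dir, "truth_copy_numbers.tsv"))
  write_tsv_strict(world$truth$planted, file.path(dir, "truth_planted.tsv"))
  manifest <- list(format = "ridscape-world-manifest", version = 1L,
                   package_version = as.character(utils::packageVersion("ridscape")),
                   config = unclass(world$config),
                   calibration = world$truth$calibration)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Build scoring profiles from a world's seed alignments
#'
#' Convenience wrapper: one [build_profile()] call per subfamily with the
#' world's footprint regions and key sites.
#'
#' @param world A `rid_world` (or the `profiles` element of one).
#' @param pseudocount_mass Passed to [build_profile()].
#' @return Named list of `rid_profile`.
#' @export
world_profiles <- function(world, pseudocount_mass = 1) {
  prof <- if (inherits(world, "rid_world")) world$profiles else world
  geom_fp <- prof$footprints
  ks <- prof$key_sites
  out <- lapply(names(prof$alignments), function(fam) {
    build_profile(prof$alignments[[fam]], fam,
                  pseudocount_mass = pseudocount_mass,
                  footprints = geom_fp, key_sites = ks)
  })
  stats::setNames(out, names(prof$alignments))
}
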