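#' Pipeline configuration
#'
#' Paths and thresholds for [run_pipeline()]. Thresholds default to the
#' values used throughout: E-value cutoff 1e-4 (the relaxed cutoff for
#' exhaustive family detection), cluster window of 3 intervening genes /
#' 5 kb, MOTU cutoff 0.03.
#'
#' @param alignments_dir Directory of per-subfamily seed alignments
#'   (`seed_<subfamily>.fasta`).
#' @param proteome_path Proteome FASTA ("genome|protein" ids).
#' @param features_path Feature file (GFF3 subset or 7-column TSV).
#' @param genomes_path Genome table TSV (genome_id, taxon_domain, size_bp,
#'   interest_score).
#' @param out_dir Output directory.
#' @param tree Optional newick text for the iTOL export.
#' @param features_dialect "gff3" or "tsv".
#' @param evalue_cutoff,margin_threshold,max_intervening,max_gap_bp,motu_cutoff
#'   Stage thresholds.
#' @param score_fraction Fraction of the consensus self-score used as the
#'   per-subfamily classification threshold (default 0.5).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `rid_pipeline_config` list.
#' @export
pipeline_config <- function(alignments_dir, proteome_path, features_path,
                            genomes_path, out_dir, tree = NULL,
                            features_dialect = c("gff3", "tsv"),
                            evalue_cutoff = 1e-4, score_fraction = 0.5,
                            margin_threshold = 0, max_intervening = 3L,
                            max_gap_bp = 5000L, motu_cutoff = 0.03,
                            seed = 1L) {
  features_dialect <- match.arg(features_dialect)
  stopifnot(evalue_cutoff > 0, score_fraction > 0, margin_threshold >= 0,
            max_intervening >= 0, max_gap_bp >= 0,
            motu_cutoff > 0, motu_cutoff < 1)
  for (p in c(alignments_dir, proteome_path, features_path, genomes_path)) {
    if (!file.exists(p)) stop("config error: missing input path: ", p)
  }
  structure(
    list(alignments_dir = alignments_dir, proteome_path = proteome_path,
         features_path = features_path, genomes_path = genomes_path,
         out_dir = out_dir, tree = tree,
         features_dialect = features_dialect,
         evalue_cutoff = evalue_cutoff, score_fraction = score_fraction,
         margin_threshold = margin_threshold,
         max_intervening = as.integer(max_intervening),
         max_gap_bp = as.integer(max_gap_bp),
         motu_cutoff = motu_cutoff, seed = as.integer(seed)),
    class = "rid_pipeline_config")
}

#' Run the full comparative-genomics pipeline
#'
#' Stages run in order: profile building -> candidate search ->
#' classification -> neighborhood -> distribution. Every stage's outputs
#' are written before the next stage starts; a failing stage aborts with a
#' stage-named error and leaves a `.partial` marker. Re-running with
#' identical inputs produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of the in-memory stage results (classification,
#'   events, summaries, distribution table, correlation, manifest path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rid_pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(out, ".partial")
  file.create(partial)
  log_path <- file.path(out, "pipeline.log")
  log_con <- file(log_path, open = "wb")
  on.exit(close(log_con), add = TRUE)
  logit <- function(stage, msg) {
    writeLines(sprintf("[%s] %s", stage, msg), log_con, sep = "\n")
  }
  stage <- function(name, expr) {
    logit(name, "start")
    res <- tryCatch(expr, error = function(e) {
      logit(name, paste("error:", conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logit(name, "done")
    res
  }

  profiles <- stage("profiles", {
    paths <- sort(list.files(config$alignments_dir,
                             pattern = "^seed_.*\\.fasta$", full.names = TRUE))
    if (length(paths) == 0L) stop("no seed_<subfamily>.fasta alignments found")
    geom <- NULL
    profs <- lapply(paths, function(p) {
      fam <- sub("^seed_", "", sub("\\.fasta$", "", basename(p)))
      aln <- read_alignment(p, id = fam)
      geom <<- world_footprints(aln$n_columns)
      build_profile(aln, fam, footprints = geom$footprints,
                    key_sites = geom$key_sites)
    })
    names(profs) <- vapply(profs, function(p) p$subfamily, character(1))
    for (fam in names(profs)) {
      write_profile(profs[[fam]], file.path(out, paste0("profile_", fam, ".json")))
    }
    profs
  })

  inputs <- stage("load", {
    prot <- read_fasta(config$proteome_path)
    feats <- read_features(config$features_path, config$features_dialect)
    gens <- read_tsv_strict(config$genomes_path)
    list(proteome = prot, features = feats, genomes = gens)
  })

  search <- stage("search", {
    queries <- vapply(profiles, profile_consensus, character(1))
    names(queries) <- paste0("query_", names(profiles))
    hits <- find_candidates(queries, inputs$proteome,
                            evalue_cutoff = config$evalue_cutoff)
    write_tsv_strict(hits, file.path(out, "candidates.tsv"))
    hits
  })

  classification <- stage("classify", {
    cand_ids <- sort(unique(search$target_id))
    cand <- inputs$proteome[names(inputs$proteome) %in% cand_ids]
    thresholds <- default_score_thresholds(profiles, config$score_fraction)
    cls <- if (length(cand)) {
      classify_proteome(cand, profiles, thresholds, config$margin_threshold)
    } else {
      classify_proteome(character(0) |> stats::setNames(character(0)),
                        profiles, thresholds)
    }
    write_tsv_strict(cls, file.path(out, "classification.tsv"))
    cls
  })

  neighborhood <- stage("neighborhood", {
    events <- find_cluster_events(inputs$features,
                                  max_intervening = config$max_intervening,
                                  max_gap_bp = config$max_gap_bp)
    pies <- subfamily_frequencies(events)
    bars <- role_genome_proportions(events, inputs$genomes$genome_id)
    write_tsv_strict(events, file.path(out, "cluster_events.tsv"))
    write_tsv_strict(pies, file.path(out, "clustering_pies.tsv"))
    write_tsv_strict(bars, file.path(out, "clustering_bars.tsv"))
    list(events = events, pies = pies, bars = bars)
  })

  distribution <- stage("distribution", {
    tab <- copy_number_table(classification, inputs$genomes)
    corr <- size_correlation(tab)
    write_tsv_strict(tab, file.path(out, "copy_numbers.tsv"))
    write_tsv_strict(data.frame(r = as.numeric(corr$r), n = corr$n),
                     file.path(out, "size_correlation.tsv"))
    if (!is.null(config$tree)) {
      exp <- export_itol(tab, config$tree)
      write_itol(exp, file.path(out, "itol_multibar.txt"))
    }
    list(table = tab, correlation = corr)
  })

  manifest <- list(format = "ridscape-pipeline-manifest", version = 1L,
                   seed = config$seed,
                   config = unclass(config)[setdiff(names(unclass(config)), "tree")],
                   config_hash = sum(utf8ToInt(paste(
                     vapply(unclass(config)[order(names(unclass(config)))],
                            function(x) paste(format(x), collapse = ","),
                            character(1)), collapse = ";"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(partial)
  invisible(list(profiles = profiles, candidates = search,
                 classification = classification,
                 neighborhood = neighborhood,
                 distribution = distribution,
                 manifest = file.path(out, "manifest.json")))
}
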