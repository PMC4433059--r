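#!/usr/bin/env Rscript
# Detect Rid candidates in the proteome with the seeded local-alignment
# search (E <= 1e-4), classify them against the subfamily profiles, call
# active-site residues, detect 3x fusions, and score recovery against the
# planted truth. Run after 02_build_profiles.R.

library(ridscape)

profiles <- lapply(sort(list.files("results/profiles", "^profile_.*json$",
                                   full.names = TRUE)), read_profile)
names(profiles) <- vapply(profiles, function(p) p$subfamily, character(1))
proteome <- read_fasta("results/world/proteins.faa")
truth <- ridscape:::read_tsv_strict("results/world/truth_proteins.tsv")

# stage 1: relaxed homology search with the subfamily consensus queries
queries <- vapply(profiles, profile_consensus, character(1))
names(queries) <- paste0("query_", names(profiles))
hits <- find_candidates(queries, proteome, evalue_cutoff = 1e-4)
cat("Candidate search: ", nrow(hits), " raw hits over ",
    length(unique(hits$target_id)), " of ", length(proteome),
    " proteins\n", sep = "")

# stage 2: profile cross-mapping classification (the false-positive filter)
classification <- classify_proteome(proteome, profiles)
ridscape:::write_tsv_strict(classification, "results/classification.tsv")

merged <- merge(classification, truth, by = "protein_id")
rid <- merged[merged$subfamily.y != "DECOY", ]
decoys <- merged[merged$subfamily.y == "DECOY", ]
fus <- rid[rid$fusion_count.y == 3L, ]
cat("\nRecovery against planted truth:\n")
cat("  subfamily accuracy: ",
    round(100 * mean(rid$subfamily.x == rid$subfamily.y), 2), "% of ",
    nrow(rid), " Rid proteins\n", sep = "")
cat("  arg-site residue accuracy: ",
    round(100 * mean(rid$arg_site_residue.x == rid$arg_site_residue.y), 2),
    "%\n", sep = "")
cat("  3x fusions recovered: ", sum(fus$fusion_count.x == 3L), "/",
    nrow(fus), "\n", sep = "")
cat("  decoys classified (should be 0): ",
    sum(decoys$subfamily.x != "UNCLASSIFIED"), "/", nrow(decoys), "\n",
    sep = "")
cat("  atypical serine-RidA called: ", sum(classification$atypical), "\n",
    sep = "")
cat("\nClassification table written to results/classification.tsv\n")
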