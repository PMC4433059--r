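#!/usr/bin/env Rscript
# Score chromosomal clustering between Rid genes and partner-role genes
# (PLP enzymes, amine oxidase, carbamoyl-phosphate-related enzymes):
# per-role subfamily pies, per-role genome-proportion bars, and the
# RidA co-clustering share of Rid7 clusters. Run after 01_simulate.R.

library(ridscape)

features <- read_features("results/world/features.gff3", "gff3")
genomes <- ridscape:::read_tsv_strict("results/world/genomes.tsv")
planted <- ridscape:::read_tsv_strict("results/world/truth_planted.tsv")

events <- find_cluster_events(features)   # <= 3 intervening genes, <= 5 kb
pies <- subfamily_frequencies(events)
bars <- role_genome_proportions(events, genomes$genome_id)
ridscape:::write_tsv_strict(events, "results/cluster_events.tsv")
ridscape:::write_tsv_strict(pies, "results/clustering_pies.tsv")
ridscape:::write_tsv_strict(bars, "results/clustering_bars.tsv")

cat("Clustering events:", nrow(events), "across",
    length(unique(events$genome_id)), "genomes\n\n")
cat("Per-role genome proportions (bars) vs planted probabilities:\n")
eligible <- unique(planted$genome_id[planted$eligible])
bars_elig <- role_genome_proportions(events, eligible,
                                     roles = sort(unique(planted$role)))
bars_elig$planted_prob <- vapply(bars_elig$role, function(r) {
  mean(planted$planted[planted$role == r & planted$eligible])
}, numeric(1))
print(transform(bars_elig, proportion = round(proportion, 3),
                planted_prob = round(planted_prob, 3)), row.names = FALSE)

cat("\nSubfamily share of clustering instances (pooled over roles):\n")
pooled <- tapply(pies$count, pies$subfamily, sum)
print(round(pooled / sum(pooled), 3))

frac <- co_cluster_fraction(events, features, "Rid7", "RidA")
cat("\nShare of Rid7 clusters that also contain RidA: ",
    round(100 * as.numeric(frac), 1), "%\n", sep = "")
cat("\nEvent and summary tables written to results/\n")
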