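#!/usr/bin/env Rscript
# Phylogenetic-distribution arm: per-genome subfamily copy-number table,
# genome-size/copy-number correlation, MOTU dereplication of the genome
# set, and the iTOL-style multi-bar export. Run after 03_classify.R.

library(ridscape)

classification <- ridscape:::read_tsv_strict("results/classification.tsv")
genomes <- ridscape:::read_tsv_strict("results/world/genomes.tsv")

tab <- copy_number_table(classification, genomes)
ridscape:::write_tsv_strict(tab, "results/copy_numbers.tsv")
corr <- size_correlation(tab)
cat("Pearson correlation of genome size vs Rid copy number: r = ",
    round(as.numeric(corr$r), 3), " (n = ", corr$n, ")\n", sep = "")

# MOTU dereplication demo on synthetic barcode distances: genomes are
# assigned to latent species so that re-sequenced strains of one species
# sit below the cutoff while species are well separated
set.seed(2001L)
n <- nrow(genomes)
species <- sample(ceiling(n / 3), n, replace = TRUE)
d <- matrix(stats::runif(n * n, 0.10, 0.60), n)
same <- outer(species, species, "==")
d[same] <- stats::runif(sum(same), 0, 0.02)
d <- (d + t(d)) / 2
diag(d) <- 0
rownames(d) <- colnames(d) <- genomes$genome_id
derep <- motu_dereplicate(d, genomes, cutoff = 0.03)
ridscape:::write_tsv_strict(derep, "results/motu_representatives.tsv")
cat("MOTU dereplication at cutoff 0.03: ", n, " genomes -> ",
    nrow(derep), " representatives\n", sep = "")

# iTOL multibar export against a ladder tree over the genome set
tree <- paste0(paste(rep("(", n - 1), collapse = ""),
               genomes$genome_id[1],
               paste(sprintf(",%s)", genomes$genome_id[-1]), collapse = ""),
               ";")
itol <- export_itol(tab, tree)
write_itol(itol, "results/itol_multibar.txt")
cat("iTOL multibar annotation written for ", n - length(itol$unmatched),
    " leaves (", length(itol$unmatched), " unmatched)\n", sep = "")
cat("\nDistribution tables written to results/\n")
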