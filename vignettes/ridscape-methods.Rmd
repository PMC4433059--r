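---
title: "Methods: profile-based Rid subfamily classification and gene-neighborhood analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-based Rid subfamily classification and gene-neighborhood analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ridscape` re-implements, at desk scale, a comparative-genomics workflow
for the Rid (YjgF/YER057c/UK114) protein family: detect family members in
proteomes, split them into the eight subfamilies (RidA, Rid1–Rid7), call
the catalytic active-site residues, detect tandem-domain fusions, score
chromosomal clustering between Rid genes and partner metabolic genes,
dereplicate genome sets into MOTU representatives, and tabulate the
phylogenetic distribution of subfamily copy numbers. Because the original
analysis ran inside a curated genome warehouse that cannot be shipped, the
package pairs every pipeline stage with a synthetic genome generator that
plants known truth — so each stage is testable end to end without any
download. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic world does and does not show.

# Subfamily profiles

## Scoring model

Each subfamily is represented by a position-specific scoring matrix (PSSM)
built from a seed alignment. Columns whose gap fraction exceeds 50% are
trimmed first; for a surviving column $c$ and residue $a$ the score is the
log-odds of the pseudocount-smoothed column frequency against a background
$q_a$:

$$\mathrm{score}(c,a) \;=\; \log_2
  \frac{(n_{c,a} + \beta q_a)\,/\,(N_c + \beta)}{q_a},$$

with $n_{c,a}$ the residue count, $N_c$ the non-gap count, and $\beta$ a
single total pseudocount mass split by the background. Defaults: uniform
background $q_a = 1/20$ and $\beta = 1$. This scheme was chosen over
substitution-matrix mixtures because it has a closed form that unit tests
can verify to $10^{-9}$, and because at the divergence levels the
generator emulates (5% per column) the smoothed log-odds are already far
above any plausible decision boundary. Both the background and $\beta$
are arguments of `build_profile()`.

Column conservation for logo export is the standard information content
$IC_c = \log_2 20 - H_c$, with $H_c$ the Shannon entropy of the non-gap
column frequencies, and letter height = frequency × $IC_c$. No
small-sample correction is applied, keeping the $\log_2 20$ upper bound
exact; at 50 rows per seed alignment the correction would be ≈ 0.27 bits
and constant across columns, so it would not change any ordering.

## Footprints and key sites

Six conserved footprint regions and the three catalytic sites (tyrosine,
arginine, glutamate; the homologs of TdcF Tyr17/Arg105/Glu120) are config
inputs in alignment coordinates, remapped through the trimming map — they
are metadata, not something inferred from the alignment. A key site
falling in a trimmed column is a hard error naming the column, because
every downstream active-site call would silently shift otherwise. The
arginine-site residue spectrum reported by `footprint_consensus()` is
ranked by frequency so that minority variants (the ~10% serine class
within RidA) surface directly.

# Candidate search and classification

Detection is two-staged, mirroring a relaxed homology search followed by
a profile cross-mapping filter.

**Stage 1 — seeded local alignment.** Query and target must share at
least one exact k-mer (default $k = 4$); seeded pairs are aligned with
Smith–Waterman (BLOSUM62, gap open 11 / extend 1, via
`Biostrings::pairwiseAlignment`), and a hit is kept iff its
Karlin–Altschul expectation $E = K m n e^{-\lambda S} \le 10^{-4}$, using
the published gapped-BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$.
The relaxed cutoff deliberately over-collects: its job is sensitivity,
not precision. Full BLAST statistics (sum statistics, composition
adjustment) are out of scope.

**Stage 2 — profile scan.** Every candidate is scanned gaplessly: each
profile slides over all offsets, the best-scoring window per subfamily is
kept (ties → smallest offset), and the protein is assigned
$\arg\max$ subfamily iff the best score reaches the score threshold and
beats the runner-up by the margin threshold; otherwise it is
`UNCLASSIFIED`. This is the false-positive filter: a protein can pass the
relaxed E-value search yet stay unclassified. Defaults: per-subfamily
score threshold = 0.5 × the profile's consensus self-score (a window must
recover half the attainable information), margin 0 bits. Exact ties break
by the fixed order RidA < Rid1 < … < Rid7 and are flagged. Unknown
residues (`X`) score 0 — neutral rather than background-penalized — so a
sequencing artifact cannot flip a call by itself.

The scan is gapless by design. The generator is indel-free by default, and
the package documents rather than hides the consequence: indel robustness
is untested and out of the acceptance surface. An `indel_rate` dial exists
for exploration; with it enabled, recovery degrades and nothing in the
package claims otherwise.

**Active sites and fusions.** The protein position of a key site is
`offset + column − 1`. Arginine at the arg site predicts imine-hydrolase
competence; serine there within RidA is flagged as the atypical minority;
a key site beyond a truncated ORF reports a missing residue and unknown
competence. Fusion detection collects *all* windows at or above the
threshold across profiles and greedily selects non-overlapping windows in
decreasing score order (ties: smaller offset, then subfamily order);
three selected RidA domains flag the 3x arrangement. Greedy selection
equals exhaustive maximal selection on the cases that matter here
(well-separated high-scoring domains), which the test suite checks
against a brute-force oracle on two-domain proteins.

# Gene-neighborhood statistics

A clustering event is a (Rid gene, partner-role gene) pair on one contig
with at most `max_intervening` genes between them in genomic order *and*
a nearest-boundary gap of at most `max_gap_bp`. Defaults — 3 intervening
genes, 5000 bp, strand-agnostic — are typical operon-context heuristics;
the original analysis relied on a database's clustering display and never
published thresholds, so these are exposed in the configuration rather
than baked in. One event is emitted per pair: a Rid gene flanked by two
partner genes yields two events. Contigs are treated as linear.

Three summaries are computed because the field's figures mix them:
per-role subfamily *frequencies* (pie charts; normalized within role),
per-role *genome proportions* (share of genomes with ≥ 1 event), and raw
*instance counts*. `co_cluster_fraction()` measures, among events of a
focal subfamily (e.g. Rid7), the share whose cluster also contains a
companion subfamily gene (e.g. RidA) within the intervening budget of
either anchor.

# Genome-set operations

MOTU dereplication is single-linkage agglomeration: groups are connected
components of the graph joining genomes with distance ≤ cutoff (default
0.03). Single linkage at a configurable cutoff is the declared
interpretation of barcode-based MOTU grouping; the distance source
(marker p-distance or precomputed matrix) is the caller's contract, not
the algorithm's. Representatives maximize an interest score (a proxy for
the amount of published work), ties broken by smallest genome id so
selection is permutation-invariant.

The distribution table counts classified proteins per (genome,
subfamily); a fusion protein counts once — the unit is the gene copy —
with a per-domain mode behind a flag. The size/copy-number association is
the plain Pearson product-moment correlation, with eukaryote rows
excluded by default (their genome sizes are not comparable to
prokaryotes'); degenerate inputs (n < 3, constant variable) report a
missing value with a reason, never a number.

# The synthetic world

## What it emulates

`world_config()` defaults *are* the study conditions: 200 genomes,
130-residue domains, eight subfamilies with RidA-heavy prevalence
weights, 10% serine at the RidA arginine site, 2% 3x-fusion probability
per RidA gene, per-role clustering probabilities in the 0.10–0.50 range,
and a target size/copy correlation of 0.69. Key-residue patterns follow
the family's conservation structure: arg site R in RidA/Rid1–3, W in
Rid4/Rid7, variable in Rid5/Rid6; glu site E everywhere; tyr site Y
except Rid3 (I) and Rid2 (variable). Mean copy number is 4 per genome,
consistent with a multi-paralog family whose copy number grows with
genome size.

Two readings of `subfamily_prevalence` are possible (per-genome presence
probabilities vs copy-assignment weights); the generator uses them as
weights when assigning each planted copy a subfamily, which keeps the
copy-count model (below) clean and makes pie-chart odds directly
plantable (weights 0.8/0.2 give an expected RidA share of exactly 0.8).

## Correlation mechanism and calibration

Each genome draws a latent $z \sim \mathcal N(0,1)$ shared by both
variables:

$$\mathrm{size} = a + b z + \varepsilon,\qquad
  \mathrm{copies} \sim \mathrm{Poisson}\!\left(e^{\,c + d z}\right),
  \quad c = \log m - d^2/2,$$

with $a = 4\,\mathrm{Mb}$, $b = 1\,\mathrm{Mb}$,
$\varepsilon \sim \mathcal N(0, 0.25\,\mathrm{Mb})$ and mean copy number
$m$. The exact moments give

$$\rho(d) = \frac{m d}{\sqrt{m + m^2 (e^{d^2}-1)}}
            \cdot \frac{b}{\sqrt{b^2 + \sigma_\varepsilon^2}},$$

so the link strength $d$ is calibrated by a deterministic root solve of
$\rho(d) = \rho_{\text{target}}$ on $[0, 0.8]$ (where $\rho$ is
increasing) instead of a stochastic pre-run — same intent, but exact,
seed-free and testable. Targets above the mechanism's attainable maximum
(~0.72 at these settings) raise an explicit error. Companion-RidA
planting and the genome-extent floor perturb the realized correlation
only marginally; the acceptance band (±0.10 at n = 200) absorbs the
sampling noise, and the error shrinks through n ∈ {50, 200, 800} in the
property tests.

## Layout guarantees

Every Rid copy owns a block: the Rid gene centered, planted partner genes
on alternating sides with at most `side entries ≤ 3` genes between any
partner and the Rid gene, partner genes 900–1200 bp, background genes
300–600 bp, within-block gaps 50–150 bp — so every planted pair satisfies
the default cluster window (≤ 3 intervening, ≤ 5 kb) *by construction*
(worst case: 3 × 1200 bp genes + 4 × 150 bp gaps = 4200 bp). Blocks are
separated by five background genes with ~2 kb gaps, so no cross-block
pair can satisfy the window. Planting is decided once per (genome, role)
for genomes carrying ≥ 1 Rid gene; the partner attaches to a uniformly
chosen copy, which is what makes pie shares equal prevalence weights in
expectation. Rid7 copies that host a planted partner additionally
receive a companion RidA gene with probability 0.75, emulating the
observation that most Rid7 clusters also contain RidA; the planted rate
is a design constant chosen once (the emulated observation is only a
">70%" bound). Distant partner-role genes (placed ≥ 5 genes and ≥ 2 kb
from any Rid gene, with probability 0.3 per role) keep the statistics
honest: carrying a role gene is not the same as clustering with it.

Decoy proteins — three per genome — are composition-preserving shuffles
of freshly sampled Rid domains: same length, same residue composition,
no positional signal. They are the hardest "wrong" sequences for a
composition-blind scanner and they test the false-positive filter
directly.

## What passing tests do not show

The world is indel-free, one contig per genome (a two-contig mode exists
for boundary tests), phylogenetically uncorrelated (genomes are iid
draws, with an archaea label on ~5.5% of them), and its decoys are
shuffles rather than genuinely homologous non-Rid families. Perfect
recovery on this world therefore demonstrates the pipeline's internal
correctness — scoring, thresholds, bookkeeping, geometry — not its
robustness to real-genome phenomena: indels, domain erosion, remote
homologs just below the family boundary, contig fragmentation, or
operon rearrangement. Accuracy claims in this package are claims about
the synthetic conditions stated here.

# Numerical and determinism choices

* Gap-column trimming at 50% (configurable); trimming remaps footprints
  and key sites, dropping a fully trimmed footprint with a warning but
  refusing to move a key site silently.
* All tie-breaks are total and documented: subfamily order for
  assignment, lexicographic residue for consensus, smallest offset for
  windows, smallest genome id for representatives.
* Every stochastic quantity derives from one integer seed; worlds and
  pipeline outputs regenerate byte-identically (fixed TSV dialect: tabs,
  `#` comments, LF endings). The test suite diffs raw bytes.
* Problem sizes used by the checks: 200-genome worlds for recovery
  statistics, 500 for the null-correlation bound, 800 for the
  convergence ladder, ≤ 300-aa proteins for the scan oracle, ≤ 20-genome
  matrices for the MOTU oracle. These sizes give binomial/sampling
  intervals tight enough to be informative while keeping a full run in
  the low minutes on one core.

# Known limitations

Gapless scanning (no indel tolerance) is the main deliberate
simplification, documented above. The E-value model reuses fixed
Karlin–Altschul constants rather than estimating them per
query–database pair. Neighborhood statistics do not test association
against a genome-shuffling null — they summarize observed proximity.
Circular replicons are treated as linear. None of these affect the
synthetic acceptance surface; all of them would matter before applying
the package to real assemblies.
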