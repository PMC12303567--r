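---
title: "Methods: single-cell genotyping, lineage assignment and QTL/eQTL mapping in pooled crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell genotyping, lineage assignment and QTL/eQTL mapping in pooled crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcross)
```

cellcross analyses pooled single-cell RNA-seq of haploid F2 segregants from
a two-parent cross (the BY x RM yeast cross is the motivating system). A
single 10x-style run captures thousands of cells from thousands of
strains; each cell's transcriptome incidentally sequences a small fraction
of the strain's polymorphic sites. The pipeline turns those sparse allele
observations into genotypes, matches cells back to a reference panel,
and then maps quantitative trait loci (QTL) for fitness and expression
QTL (eQTL) per gene, partitioning trait variance along the way. Every
stage can be exercised against ground truth from the package's own
synthetic-cross generator.

## The synthetic cross

`sim_genetic_map()` places biallelic sites on a yeast-like genome (16
chromosomes, 12 Mb, ~0.38 cM/kb by default). `simulate_cross()` draws
haploid recombinant genomes: each chromosome starts from a fair coin and
switches parental origin between adjacent sites with the Haldane
recombination fraction $r = \tfrac{1}{2}(1 - e^{-2d})$, $d$ the inter-site
distance in Morgans, so crossovers are Poisson along the map with no
interference and every site has RM-allele frequency 1/2. There are no
heterozygotes: segregants of a haploid x haploid cross carry one of two
alleles at every site.

`plant_architecture()` lays a known genetic architecture over the panel:
additive fitness QTL ($y = \sum_q \beta_q g_q + \varepsilon$), per-gene
cis-eQTL placed inside the target gene's cis window by construction,
trans-regulatory hotspots (one site regulating many genes from a single
25-kb window) and diffuse background trans-eQTL. Realised heritabilities
are recorded so recovery can be scored exactly.

`simulate_cells()` adds the observation layer. Coverage is Bernoulli per
site with expected breadth 0.03 (the study-scale fraction of sites seen
per cell); read depth at covered sites is 1 plus a small Poisson excess.
Each read reports the RM allele with probability
$(1-s)\,[\,g=\mathrm{RM}\,?\,1-\epsilon\,:\,\epsilon\,] + s f$, where
$\epsilon$ is the sequencing/RT error rate, $s$ the index-swap rate and
$f$ the pool allele frequency at the site — a swapped read comes from the
pooled library, not from the droplet's cell. Barcodes number about 4.83
per strain and 10% of them are doublets; a doublet droplet carries both
constituent cells' transcripts, so its coverage is drawn per constituent
(roughly doubling covered sites) and its library size is the sum of two
draws. UMI counts are negative binomial around the strain's mean
expression with per-cell library-size scaling; dropout arises purely from
sampling.

What the generator does **not** emulate: cell-cycle and other
transcriptional programs, ambient RNA, reference-mapping bias, empty
droplets, batch effects, segregation distortion (allele frequencies stay
at 1/2) and read-level artifacts. Tests passing on this generator show
the estimators are correct under their stated model, not that real
libraries satisfy that model.

### Two scaled-down map regimes

The real cross has ~41,600 sites over a ~4,300 cM genome; a desk-scale
simulation cannot keep both the marker density and the genome length at
1/20 of the sites. The package's analyses use whichever axis carries the
information being tested, as a deliberate design choice:

* **density-preserving regime** (`spacing_cm = 0.103`): the inter-marker
  genetic distance of the real data is kept, so a cell's covered sites are
  ~3.4 cM apart and HMM error correction and imputation behave as at full
  scale. Used for genotyping and channel-parameter estimation.
* **full-length regime** (default map): the ~4,500 cM genome is kept at
  reduced marker density, so panel strains are essentially unrelated and
  the number of independently segregating regions is realistic. Used for
  assignment nulls, doublet detection and QTL/eQTL mapping. On a
  density-preserving 200 cM genome, random segregants share large blocks
  (typical pairwise rounded-genotype $R^2 \approx 0.1$), which makes
  "false assignment" ill-defined and defeats the doublet rule's
  dissimilarity clause — an artifact of that scaling axis, not of the
  methods.

## Genotyping HMM

`posterior_genotypes()` runs an independent two-state (BY/RM) hidden
Markov chain per cell and chromosome. Transitions between adjacent sites
are the Haldane fractions of the map distances times a single global
recombination scale; the initial state is P(RM) = 1/2; emissions are the
error/swap channel above with reads conditionally independent given the
state. Forward–backward smoothing yields P(RM | all reads of the cell) at
every site — covered or not, which is what imputes low-coverage sites —
and the per-cell log-likelihood. The recursions run in scaled probability
space with per-site normalization (compiled in C for speed); emission
probabilities are clamped to $[10^{-300}, 1-10^{-12}]$ so impossible-data
corner cases degrade gracefully rather than produce NaN. A cell with no
reads gets the flat prior everywhere, with a warning.

`estimate_hmm()` fits $(\epsilon, s)$ and the recombination scale by
Baum–Welch EM (monotone log-likelihood, relative tolerance $10^{-6}$, at
most 200 iterations). Two estimator details matter and are worth
explaining:

* **Where the information comes from.** At pool frequency $f = 1/2$ the
  error and swap channels are observationally identical — both reduce to
  one mismatch rate $(1-s)\epsilon + s/2$ — so the two rates are separated
  only by how the mismatch rate varies with $f$ across sites. That
  variation is weak in a balanced cross, and estimating $f$ from the same
  reads feeds its sampling noise back into the apparent mismatches, which
  drives EM into a spurious swap-heavy corner. The estimator therefore
  takes $f$ from the reference panel when one is supplied (the pool *is*
  the panel) and, after EM, refines $(\epsilon, s)$ by matching each cell
  to its best panel strain and maximizing the binomial likelihood of the
  reads against the known strain alleles — conditioning on the states
  removes the near-degeneracy. Cells whose reads misfit their best strain
  (doublets, misassignments) are excluded by a one-sided binomial test at
  level 0.01 before this refinement, iterated three times. A nested
  golden-section profile search is used because quasi-Newton methods stall
  on the nearly flat $(\epsilon, s)$ trade-off.
* **Doublets look like index swapping.** A doublet's second-genome reads
  are state-independent and pool-distributed — exactly the swap channel —
  and inflate $\hat{s}$ by several points at a 10% doublet rate. EM is
  therefore run twice, dropping cells whose posterior-weighted mismatch
  count exceeds the fitted channel rate (one-sided binomial, level 0.05)
  after the first pass.

The sampling variance of the $(\epsilon, s)$ split is panel-limited
(cells sharing a strain are not independent), so single-run estimates
scatter noticeably; averages over replicate runs are accurate to about
±0.01 on $\epsilon$ and ±0.03 on $s$ at the 200-strain scale.

## Assigning cells to the panel

The distance between a probabilistic cell genotype $g_c$ and a strain
genotype $g_s$ is the expected number of mismatches,
$\sum_i g_{c,i} + g_{s,i} - 2 g_{c,i} g_{s,i}$, the Hamming distance on
hard calls; a site with posterior 1/2 contributes exactly 1/2 to every
strain, so uncovered sites cancel out of the comparison. Each cell takes
its arg-min strain, and significance comes from `n_null` randomly
generated batches of the panel's size: the p-value is the add-one
proportion of null batches whose best match beats the observed one,
Benjamini–Hochberg-adjusted across cells, with assignment at q < 0.05.

Null batches are freshly simulated F2 genomes on the same map rather than
site-wise shuffles of the panel. This was a genuinely open design point:
shuffling preserves allele frequencies but destroys linkage, and because
HMM-imputed posteriors are block-structured, distances to real
(block-structured) strains spread much more than distances to shuffled
strains — the real best match then beats the shuffled null for *any*
cell, including cells whose true strain is absent. Simulated recombinant
genomes preserve both the frequency and the linkage scale, and calibrate
the excluded-strain control to its nominal FDR. `null = "shuffle"`
remains available.

Relatedness between a cell and its best strain is reported as the
adjusted $R^2$ of the rounded genotypes (ties at 0.5 round to RM), with
the regression slope's sign alongside, since $R^2$ is blind to
anti-correlation.

**Doublets** are flagged by three clauses in order: (1) covered-site
count at or above the third quartile (a doublet carries two cells'
reads); (2) no significant assignment, implemented as a read-level
misfit test — the number of reads contradicting the best strain exceeds
the channel rate $(1-s)\epsilon + s/2$ by a one-sided binomial test at
level 0.05 (a 50:50 mixture contradicts either parent at ~25% of reads);
and (3) the top two matching strains are themselves unrelated (rounded
$R^2 < 0.1$), so the misfit is not two near-identical references
splitting one lineage. The level of clause 2 is the singlet false-flag
rate; flagged cells are never assigned. Clause 2 is deliberately not the
permutation q-value: half a genome genuinely matching a real strain is
always overwhelmingly significant against any random-batch null, so a
q-based clause would never fire.

**Consensus profiles.** Cells assigned to a strain form a lineage; the
consensus genotype is the per-site median of their posteriors (robust to
an outlier cell) and the consensus expression profile is the UMI column
of the lineage cell with the largest total count. Downstream model
fitting uses expression standardized per gene and then divided by the
cell's total count, in that order.

## REML variance partitioning

`fit_reml()` maximizes the restricted likelihood of
$y = X\beta + \sum_c u_c + \varepsilon$ with
$\mathrm{cov}(u_c) = \sigma^2_c K_c$, $K_c = W_c W_c^\top / m_c$ the
kernel of the column-standardized design (the GCTA convention;
zero-variance columns are dropped with a message), residual
$\sigma^2_e I$, and an intercept as the only fixed effect. "Variance
explained" is $\sum_c \sigma^2_c / (\sum_c \sigma^2_c + \sigma^2_e)$ —
the only reading under which the difference algebra below is coherent.
With one random term the fit is exact: rotate into the eigenbasis of
$K$, profile out the total variance and search the heritability ratio in
one dimension. With several terms the fit runs expectation-maximization
warm-up steps and then average-information (AI) Newton updates, with a
line search so the restricted likelihood never decreases, negativity
handled by projection at (effectively) zero, convergence at relative
change $10^{-6}$, and an error carrying the trajectory after 200
iterations. Standard errors come from the inverse AI matrix.

`partition_fitness()` fits three models — genotype only, expression only,
joint — and reads off, with $R_g$, $R_e$, $R_{ge}$ their explained
fractions: shared $= R_g + R_e - R_{ge}$, genotype-exclusive
$= R_{ge} - R_e$, expression-exclusive $= R_{ge} - R_g$, residual
$= 1 - R_{ge}$. Sampling noise can push a component slightly negative;
it is clipped at zero and the set renormalized, with a message. The
components are invariant to affine rescaling of the response and always
sum to 1. `partition_cis_trans()` applies the same algebra to a gene's
cis- and trans-eQTL genotype designs; a gene with no cis-eQTL has cis
fraction exactly 0 by definition.

`expression_heritability()` handles the matrix-valued response by PCA:
take the minimal set of leading PCs reaching 99% of the expression
variance, fit each PC against the genotype kernel (re-using one
eigendecomposition), and weight by eigenvalue share **of the total
variance** — not renormalized within the selected set — so that with the
threshold at 1 and genotype fully determining expression the weighted sum
is exactly 1. Requiring as many PCs as samples is rejected as
unattainable. Both the first-PC-only and the weighted-sum path are
available through the threshold.

## L0-penalized forward search

QTL models minimize $F_o(\beta) = \mathrm{RSS}(\beta) + \lambda
\lVert\beta\rVert_0$. `forward_search()` adds, at each step, the locus
whose inclusion most reduces the RSS of the fully refit model (computed
by projecting all candidates onto the orthogonal complement of the
selected set, which is algebraically the full refit), stops when no
addition lowers $F_o$, and breaks ties by the lowest column index so
results are deterministic. Because addition order matters under linkage,
a refinement pass after each addition tries swapping every selected locus
for every alternative, accepting strict RSS improvements, for at most 5
sweeps. On orthogonalized designs the greedy optimum coincides with
exhaustive best-subset search, which the test suite verifies against all
$2^{10}$ subsets.

`cv_lambda()` chooses the penalty: 10 random partitions; per fold, a
forward path on the training samples floored at $\lambda = \log
n_{\mathrm{train}}$ (the BIC floor), held-out squared error for every
path size, and the smallest admissible $\lambda$ whose greedy model
attains the minimal error. Two numerical choices matter. First, a sparser
size whose error is within one *paired* standard error of the minimum is
preferred: the paired difference of per-observation squared errors is the
right noise scale (raw MSE standard errors would prune genuine QTL), and
without this rule holdout noise frequently picks one or two spurious loci
under a permuted-response null. Second, the per-fold $\lambda$ recorded
for the empty model is just above the fold's best null gain, so the
averaged $\lambda^\ast$ sits at the data's own null scale when there is
nothing to find, and at the $\log n$ boundary when signal dominates.
`map_qtl()` composes the two on standardized genotypes.

`map_eqtl()` scans each gene at the fixed BIC penalty $\lambda = \log n$
(no cross-validation), where $n$ is the number of consensus segregants
entering the regression — the regression operates on consensus profiles,
so their count, not the raw cell count, is the relevant sample size.
Zero-variance genes are skipped with a message. One property worth
knowing: the objective is scale-dependent — RSS scales with the response
variance while $\lambda$ does not — so the per-gene false-selection rate
depends on the expression unit and on the locus count (roughly
$p \cdot P(\chi^2_1 > \log n)$ spurious loci per pure-noise gene). At
desk scale the BIC floor keeps null genes near-empty for locus counts up
to a few dozen; genome-wide locus counts need either larger $n$ or a
stricter penalty, which is exactly why the fitness QTL scan
cross-validates $\lambda$ upward from the floor.

`power_analysis()` subsamples strains without replacement at each
requested size, re-runs the per-gene scan, and regresses the detected
eQTL count on the sample size (undefined, returned as NA, with a single
size).

## Regulatory architecture

**Hotspots.** Chromosomes are tiled from position 1 in non-overlapping
25-kb windows; per window the eQTL and the distinct regulated genes are
counted, and a window is a hotspot when both counts are at or above the
third quartile of their distributions over occupied windows (windows with
at least one eQTL). With a constant count distribution every occupied
window passes — the documented degenerate case of a quartile rule.

**cis/trans.** An eQTL is cis when it lies on its gene's chromosome
within the strand-aware window from 1,000 bp upstream of the
transcription start to 200 bp downstream of the gene end (minus-strand
genes: $[\mathrm{start}-200, \mathrm{end}+1000]$); everything else,
including eQTL of unannotated genes (with a warning), is trans, so every
eQTL receives exactly one label. Genes without strand default to plus. A
paired Wilcoxon signed-rank comparison of per-gene cis vs trans absolute
effects and a 2x2 odds-ratio/chi-square helper for window contingencies
are provided.

**Matching QTL to eQTL.** The gene's expression is regressed on the QTL
genotypes to predict each QTL's expression effect; a same-chromosome
(QTL, eQTL) pair scores
$e^{-d_{\mathrm{cM}}/\delta}\, e^{-|\hat\beta_q - \beta_e|/\tau}$
(zero across chromosomes), and the score-maximal order-preserving pairing
is found by Needleman–Wunsch global alignment over the position-sorted
lists with gap penalty $\gamma$ per unmatched QTL (unmatched eQTL are
free). Defaults: $\delta = 10$ cM, $\tau$ = pooled effect SD, $\gamma =
0.5$, all configurable. A pair scoring below $e^{-3}$ — about three decay
lengths — is never formed: a positive-but-negligible score would
otherwise always beat a gap, and such a pairing carries no evidence of
locus identity. `model_similarity()` extends the pair score by an
allele-frequency factor $e^{-|f_a - f_b|/\phi}$ ($\phi = 0.1$) and
normalizes by the larger self-score, so self-similarity is 1 and models
on disjoint chromosomes score 0. `rank_permutation_test()` compares the
mean effect-size rank of a gene's matched QTL to 999 random same-size
subsets of the unmatched QTL; subsets tying the observed mean count one
half (mid-p), which keeps the null uniform despite integer ranks; the
add-one convention is available. `hotspot_qtl_rank_correlation()` is the
Spearman correlation between QTL effect ranks and the regulated-gene
counts of their windows, excluding QTL in eQTL-free windows, with the
exact permutation p-value below 10 pairs.

## Pipeline and interfaces

`run_pipeline()` executes simulate, genotype, assign, partition,
map_qtl, map_eqtl and regulatory in order. Each stage reads only the
previous stages' serialized outputs (TSV, Matrix Market, JSON; physical
coordinates 1-based inclusive) and is skipped when its outputs exist, so
runs are re-entrant and individual stages can be forced. Per-stage seeds
derive deterministically from the single config seed; two runs with the
same config are bit-identical. Configs validate strictly — unknown keys
are errors — and round-trip through JSON. The package is R-native: the
exported functions and the pipeline runner are the interface, and
`tidy()`/`glance()`/`autoplot()` methods expose every fitted object as
tibbles and ggplots.

## Problem sizes and what the tests show

The test suite exercises the stages at deliberately chosen sizes: 200
strains x 2,000 sites x ~1,000 barcodes for genotyping and channel
recovery; 1,500–2,000 segregants x 800–1,000 sites with 20 planted QTL
for mapping; n = 1,000 with 500 loci for heritability recovery; n = 500
for partition algebra; 400 strains with 3 planted hotspot windows for
hotspot detection; and toy instances (≤10 sites, ≤6x6 alignments,
$2^{10}$ subsets) wherever an exhaustive oracle exists. Oracle
equivalences are exact to $10^{-10}$–$10^{-8}$; statistical recoveries
are tested at the tolerances the sampling noise of those sizes supports
(±0.05 on a planted heritability of 0.5, ±0.07 per partition component,
±0.01/±0.03 on the error/swap rates as means over 10 replicate runs).

## Known limitations

* The error/swap split is weakly identified in a balanced cross; without
  a reference panel only their mixture is well determined.
* The L0+BIC objective is scale-dependent (see above); users mapping
  eQTL on differently normalized expression should expect the
  false-selection rate to move with the unit.
* The quartile hotspot rule flags the top quartile of occupied windows by
  construction; with a heavy, uniform background of weak eQTL its
  precision against planted hotspots degrades.
* No dominance or epistatic variance components, no kinship correction
  inside the scan, no ambient-RNA or cell-cycle modelling. A pluggable
  expression pre-transform hook (`smooth_expression()`) is exposed for
  denoisers, shipping with the identity and a simple low-rank smoother
  only.
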