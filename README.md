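# cellcross

One-pot single-cell eQTL and QTL analysis for pooled segregant crosses.

A single droplet-based scRNA-seq run of a pooled haploid F2 cross (think
BY x RM yeast segregants) captures thousands of cells from thousands of
strains at once. Each cell's transcriptome incidentally reads out a few
percent of the strains' polymorphic sites, which is enough — with the
right statistics — to genotype every cell, demultiplex the pool back
onto a reference panel, and map the genetic basis of fitness and of
genome-wide expression from one experiment. cellcross implements that
whole chain, for people who want to analyse such pooled-cross data or to
study the statistical behaviour of the approach on fully controlled
synthetic crosses:

* **Genotyping.** A two-state hidden Markov model per cell and
  chromosome: transitions from the genetic map through the Haldane
  function r = (1 − e^(−2d))/2, emissions through an error/index-swap
  channel P(RM read | state) = (1 − s)·[state = RM ? 1 − ε : ε] + s·f
  with f the pool allele frequency. Forward–backward smoothing imputes
  uncovered sites; Baum–Welch EM plus a panel-conditioned refinement
  estimates (ε, s) and the recombination scale from the reads themselves.
* **Lineage assignment.** Cells match the panel strain minimizing the
  expected distance Σᵢ g_c + g_s − 2 g_c g_s, with significance from
  randomly generated batches of recombinant genomes, Benjamini–Hochberg
  FDR across cells, a three-clause doublet rule, and per-strain consensus
  genotype (site-wise median) and expression (deepest cell) profiles.
* **Variance partitioning.** REML mixed models with genomic-relationship
  kernels K = WW'/m partition fitness variance into genotype-exclusive,
  expression-exclusive, shared and residual components via the
  difference algebra of the single-term and joint fits; per-gene
  expression variance splits the same way between cis- and trans-eQTL,
  and overall expression heritability is the eigenvalue-weighted sum of
  per-PC heritabilities.
* **QTL / eQTL mapping.** An L0-penalized forward search for
  F_o(β) = ‖y − Xβ‖² + λ‖β‖₀ with swap refinement and exhaustive-search
  equivalence on orthogonal designs; λ chosen by 10-fold cross-validation
  with the BIC floor λ ≥ log(n) for the fitness trait, and fixed at
  log(n) for the per-gene eQTL scans.
* **Regulatory architecture.** eQTL hotspots as top-quartile 25-kb
  windows, strand-aware cis/trans classification (−1,000 bp upstream to
  +200 bp downstream), Needleman–Wunsch matching of QTL to eQTL with
  rank-permutation significance, and an alignment-based model-similarity
  score.
* **Synthetic crosses.** A first-class generator for F2 panels, planted
  genetic architectures (QTL, cis/trans-eQTL, hotspots) and the
  single-cell observation layer (coverage breadth, read errors, index
  swapping, doublets, UMI sampling), so every stage is testable against
  ground truth.

## A worked example

Simulate a small pooled experiment, genotype and demultiplex the cells,
and map fitness QTL on the consensus genotypes:

```r
library(cellcross)

# 150 segregants, 600 sites, ~720 barcodes at 10% breadth of coverage
map   <- sim_genetic_map(n_sites = 600, n_chrom = 8, seed = 1)
panel <- simulate_cross(map, 150, seed = 2)
arch  <- architecture_spec(n_qtl = 6, qtl_effect = c(0.6, 1.2), n_genes = 50)
truth <- plant_architecture(panel, map, arch, seed = 3)
cells <- simulate_cells(panel, truth$expression,
                        observation_params(breadth = 0.10), seed = 4)

fit <- estimate_hmm(cells$allele_counts, map, panel = panel)
fit
#> <hmm_fit> error_rate = 0.05061, swap_rate = 0.04322, rec_scale = 1.071
#>   8 EM iterations; converged: TRUE
```

The simulation used ε = 0.05 and s = 0.05; both are recovered from the
reads alone. Posterior genotypes, assignment and doublet flags:

```r
post  <- posterior_genotypes(cells$allele_counts, map, fit$params,
                             barcodes = cells$truth$barcode)
calls <- assign_cells(post, panel, n_null = 50,
                      counts = cells$allele_counts, seed = 5)
dplyr::count(calls, assigned, doublet)
#> # A tibble: 3 × 3
#>   assigned doublet     n
#>   <lgl>    <lgl>   <int>
#> 1 FALSE    FALSE       6
#> 2 FALSE    TRUE       77
#> 3 TRUE     FALSE     641
```

641 of 724 barcodes are confidently assigned and 77 are flagged as
doublets (the simulation planted 10%). Consensus profiles then feed the
QTL scan:

```r
cons <- consensus_profiles(calls, post, cells$umi)
qtl  <- map_qtl(cons$genotype, truth$fitness[rownames(cons$genotype)],
                seed = 6)
tidy(qtl, map = map)
#> # A tibble: 2 × 7
#>    site locus order   beta chrom    pos    cm
#>   <int> <chr> <int>  <dbl> <chr>  <int> <dbl>
#> 1   328 328       1 -0.437 chr05 487961  185.
#> 2   183 183       2  0.454 chr03 836154  318.
```

Six QTL were planted with effects between 0.6 and 1.2; at 150 segregants
the cross-validated penalty keeps only the two largest-effect loci — one
recovered at its exact site (183, planted effect +1.02) and one two
sites from the truth (328 vs 330, planted effect −1.14). Power grows
with the panel: at 2,000 segregants the same scan recovers 20 of 20
planted QTL with no spurious selections (see the acceptance suite).
`autoplot(qtl, map)`, `glance(qtl)` and the `tidy()` methods expose every
fitted object for further analysis; `run_pipeline(pipeline_config(...))`
chains all stages with re-entrant, seed-deterministic file outputs.

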