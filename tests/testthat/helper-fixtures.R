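# Small shared fixtures, built once per test run.

tiny_map <- function(n_sites = 6, chrom = "chr01", cm_step = 2) {
  genetic_map(data.frame(chrom = chrom,
                         pos = seq_len(n_sites) * 1000L,
                         cm = (seq_len(n_sites) - 1) * cm_step))
}

.fix <- new.env()

# dense-marker regime (study-like inter-site genetic distance); the regime
# where HMM error correction and imputation carry most information
dense_fixture <- function() {
  if (is.null(.fix$dense)) {
    map <- sim_genetic_map(n_sites = 1000, n_chrom = 8, spacing_cm = 0.103,
                           seed = 71)
    panel <- simulate_cross(map, 120, seed = 72)
    cells <- simulate_cells(panel, NULL, observation_params(), seed = 73)
    .fix$dense <- list(map = map, panel = panel, cells = cells)
  }
  .fix$dense
}

# full-length genome regime (yeast-like ~4,500 cM) where panel strains are
# essentially unrelated; the regime where assignment nulls are meaningful
assign_fixture <- function() {
  if (is.null(.fix$assign)) {
    map <- sim_genetic_map(n_sites = 1000, n_chrom = 16, seed = 74)
    panel <- simulate_cross(map, 120, seed = 75)
    cells <- simulate_cells(panel, NULL,
                            observation_params(breadth = 0.05), seed = 76)
    .fix$assign <- list(map = map, panel = panel, cells = cells)
  }
  .fix$assign
}

# full-length genome regime for mapping analyses
mapping_fixture <- function() {
  if (is.null(.fix$mapping)) {
    map <- sim_genetic_map(n_sites = 400, n_chrom = 16, seed = 81)
    panel <- simulate_cross(map, 400, seed = 82)
    planted <- plant_architecture(panel, map,
                                  architecture_spec(n_qtl = 8,
                                                    qtl_effect = c(0.6, 1.2),
                                                    cis_effect = c(0.8, 1.6),
                                                    hotspot_effect = c(0.8, 1.6),
                                                    n_genes = 60),
                                  seed = 83)
    .fix$mapping <- list(map = map, panel = panel, planted = planted)
  }
  .fix$mapping
}

random_counts <- function(n_cells, n_sites, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (c in seq_len(n_cells)) {
      covered <- sort(sample.int(n_sites, max(2, rbinom(1, n_sites, 0.5))))
      rows[[c]] <- tibble::tibble(
        barcode = sprintf("c%03d", c), site = covered,
        rm = rpois(length(covered), 0.7), by = rpois(length(covered), 0.5))
    }
    out <- dplyr::bind_rows(rows)
    out[out$rm + out$by > 0, ]
  })
}
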