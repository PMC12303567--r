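test_that("genetic map validation rejects malformed input", {
  expect_error(genetic_map(data.frame(chrom = "c", pos = c(2L, 1L),
                                      cm = c(0, 1))), "sorted")
  expect_error(genetic_map(data.frame(chrom = "c", pos = c(1L, 1L),
                                      cm = c(0, 1))), "duplicated")
  expect_error(genetic_map(data.frame(chrom = "c", pos = c(1L, 2L),
                                      cm = c(1, 0))), "non-decreasing")
  expect_error(simulate_cross(data.frame(chrom = "c", pos = c(2L, 1L),
                                         cm = c(0, 1)), 5))
})

test_that("meiosis is deterministic under a seed and block-like at zero distance", {
  map <- genetic_map(data.frame(chrom = rep(c("c1", "c2"), each = 4),
                                pos = rep(1:4 * 100L, 2),
                                cm = rep(0, 8)))
  g <- simulate_cross(map, 50, seed = 9)
  # zero genetic distance: each chromosome is a single parental block
  for (ch in c("c1", "c2")) {
    idx <- which(map$chrom == ch)
    expect_true(all(apply(g[, idx], 1, function(x) length(unique(x)) == 1)))
  }
  expect_identical(g, simulate_cross(map, 50, seed = 9))
  expect_false(identical(g, simulate_cross(map, 50, seed = 10)))
})

test_that("crossover counts follow the Poisson expectation of the map length", {
  # one chromosome of 1 Morgan, dense sites
  map <- genetic_map(data.frame(chrom = "c1", pos = 1:101 * 1000L,
                                cm = seq(0, 100, length.out = 101)))
  g <- simulate_cross(map, 10000, seed = 10)
  switches <- rowSums(g[, -1] != g[, -ncol(g)])
  expect_lt(abs(mean(switches) - 1), 3 * sqrt(1 / 10000) * 2)
  # chi-square goodness of fit against Poisson(1), alpha = 0.01
  # (site spacing 1 cM, so double crossovers within an interval are rare)
  obs <- table(factor(pmin(switches, 4), levels = 0:4))
  pr <- c(dpois(0:3, 1), 1 - ppois(3, 1))
  pval <- suppressWarnings(chisq.test(obs, p = pr)$p.value)
  expect_gt(pval, 0.01)
  expect_lt(abs(mean(g) - 0.5), 0.02)
})

test_that("planted architectures reproduce their stated construction", {
  map <- sim_genetic_map(n_sites = 200, n_chrom = 4, seed = 11)
  panel <- simulate_cross(map, 400, seed = 12)
  # zero noise, a single QTL of effect 1: fitness equals that genotype column
  spec1 <- architecture_spec(n_qtl = 1, qtl_effect = c(1, 1),
                             fitness_noise_sd = 0, n_genes = 5,
                             cis_prob = 0, n_hotspots = 0, bg_trans_prob = 0)
  pl <- plant_architecture(panel, map, spec1, seed = 13)
  site <- pl$architecture$qtl$site
  beta <- pl$architecture$qtl$beta
  expect_equal(unname(pl$fitness), unname(panel[, site] * beta),
               tolerance = 1e-12)
  expect_equal(pl$architecture$fitness_h2, 1)
  # genes without planted eQTL are independent of every site
  cors <- abs(cor(pl$expression[, !colnames(pl$expression) %in%
                                  pl$architecture$eqtl$gene, drop = FALSE],
                  panel))
  expect_lt(mean(cors), 3 / sqrt(400))
  # cis-eQTL sites fall inside their gene's cis window
  spec2 <- architecture_spec(n_qtl = 0, n_genes = 40, cis_prob = 1,
                             n_hotspots = 0, bg_trans_prob = 0)
  pl2 <- plant_architecture(panel, map, spec2, seed = 14)
  labelled <- classify_cis_trans(pl2$architecture$eqtl[c("gene", "site")],
                                 pl2$architecture$genes, map)
  expect_true(all(labelled$type == "cis"))
  # requesting more QTL than sites is rejected
  expect_error(plant_architecture(panel, map,
                                  architecture_spec(n_qtl = 1000), seed = 1))
})

test_that("planted heritability is recovered empirically at large n", {
  map <- sim_genetic_map(n_sites = 300, n_chrom = 8, seed = 15)
  panel <- simulate_cross(map, 4000, seed = 16)
  spec <- architecture_spec(n_qtl = 30, qtl_effect = c(0.2, 0.4),
                            fitness_noise_sd = 1)
  pl <- plant_architecture(panel, map, spec, seed = 17)
  g <- drop(panel[, pl$architecture$qtl$site] %*% pl$architecture$qtl$beta)
  h2_emp <- var(g) / var(pl$fitness)
  expect_equal(h2_emp, pl$architecture$fitness_h2, tolerance = 1e-12)
  expect_gt(h2_emp, 0.2)
  expect_lt(h2_emp, 0.8)
})

test_that("the observation layer matches its stated channel", {
  map <- sim_genetic_map(n_sites = 400, n_chrom = 4, seed = 18)
  panel <- simulate_cross(map, 60, seed = 19)
  # error-free full coverage: every read reports the strain allele
  obs0 <- observation_params(breadth = 1, error_rate = 0, swap_rate = 0,
                             doublet_rate = 0, extra_depth = 0)
  cells <- simulate_cells(panel, NULL, obs0, seed = 20)
  tr <- cells$truth
  allele <- panel[cbind(match(tr$strain[match(cells$allele_counts$barcode,
                                              tr$barcode)], rownames(panel)),
                        cells$allele_counts$site)]
  expect_true(all(cells$allele_counts$rm[allele == 1] >= 1))
  expect_true(all(cells$allele_counts$by[allele == 1] == 0))
  expect_true(all(cells$allele_counts$rm[allele == 0] == 0))
  # breadth expectation: mean covered sites per singlet ~ breadth * n_sites
  obs1 <- observation_params(breadth = 0.05, doublet_rate = 0)
  cells1 <- simulate_cells(panel, NULL, obs1, seed = 21, n_cells = 600)
  covered <- table(cells1$allele_counts$barcode)
  expect_lt(abs(mean(covered) - 0.05 * 400),
            4 * sqrt(400 * 0.05 * 0.95 / 600))
  # doublet construction: count and distinct strains
  cells2 <- simulate_cells(panel, NULL,
                           observation_params(doublet_rate = 0.1),
                           seed = 22, n_cells = 1000)
  n_doub <- sum(cells2$truth$is_doublet)
  expect_lt(abs(n_doub - 100), 4 * sqrt(1000 * 0.1 * 0.9))
  expect_true(all(cells2$truth$strain[cells2$truth$is_doublet] !=
                    cells2$truth$strain2[cells2$truth$is_doublet]))
  # determinism
  expect_identical(simulate_cells(panel, NULL, obs1, seed = 5),
                   simulate_cells(panel, NULL, obs1, seed = 5))
})

test_that("pooled read fractions converge to panel allele frequencies", {
  map <- sim_genetic_map(n_sites = 100, n_chrom = 2, seed = 23)
  panel <- simulate_cross(map, 40, seed = 24)
  obs <- observation_params(breadth = 0.5, error_rate = 0, swap_rate = 0,
                            doublet_rate = 0)
  cells <- simulate_cells(panel, NULL, obs, seed = 25, n_cells = 3000)
  cnt <- cells$allele_counts
  frac <- tapply(cnt$rm, cnt$site, sum) / tapply(cnt$rm + cnt$by, cnt$site, sum)
  f <- colMeans(panel)[as.integer(names(frac))]
  expect_lt(max(abs(frac - f)), 0.1)
  expect_lt(mean(abs(frac - f)), 0.02)
})
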