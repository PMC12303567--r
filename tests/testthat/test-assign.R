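test_that("expected distance has its closed form and metric behaviour", {
  expect_equal(expected_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(expected_distance(c(1, 1), c(0, 0)), 2)
  # a site at 1/2 contributes exactly 1/2 whatever the other vector holds
  expect_equal(expected_distance(c(0.5, 0.5), c(0.2, 0.9)), 1)
  expect_error(expected_distance(c(1, 0), c(1, 0, 1)), "length")
  expect_error(expected_distance(c(1.2, 0), c(1, 0)), "\\[0, 1\\]")
  # metric on hard genotypes: identity, symmetry, triangle inequality
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.5); c <- rbinom(30, 1, 0.5)
      expect_equal(expected_distance(a, a), 0)
      expect_equal(expected_distance(a, b), expected_distance(b, a))
      expect_lte(expected_distance(a, c),
                 expected_distance(a, b) + expected_distance(b, c) + 1e-12)
    }
  })
})

test_that("relatedness is an adjusted R-squared with a reported slope sign", {
  a <- c(1, 0, 1, 1, 0, 0)
  expect_equal(as.numeric(relatedness(a, a)), 1)
  anti <- relatedness(a, 1 - a)
  expect_equal(as.numeric(anti), 1)
  expect_equal(attr(anti, "slope_sign"), -1)
  expect_warning(z <- relatedness(a, rep(1, 6)), "zero variance")
  expect_equal(as.numeric(z), 0)
  # independent vectors: near-zero adjusted R-squared in expectation
  withr::with_seed(32, {
    vals <- replicate(200, {
      as.numeric(relatedness(rbinom(1000, 1, 0.5), rbinom(1000, 1, 0.5)))
    })
    expect_lt(abs(mean(vals)), 0.01)
  })
})

test_that("a cell copied from a panel strain is assigned to it with certainty", {
  fx <- assign_fixture()
  G <- fx$panel[c(3, 17, 55), ]
  rownames(G) <- paste0("copy", 1:3)
  res <- assign_cells(G, fx$panel, n_null = 30, seed = 33, map = fx$map)
  expect_equal(res$strain, rownames(fx$panel)[c(3, 17, 55)])
  expect_equal(res$distance, rep(0, 3))
  expect_true(all(res$assigned))
  expect_error(assign_cells(G, fx$panel[1, , drop = FALSE], n_null = 30,
                            map = fx$map), "2 strains")
  expect_error(assign_cells(G, fx$panel, n_null = 5, map = fx$map), "19")
  expect_error(assign_cells(G, fx$panel, n_null = 30), "map")
})

test_that("cells from strains outside the panel are assigned at most at the nominal FDR", {
  fx <- assign_fixture()
  outside <- simulate_cross(fx$map, 60, seed = 34)  # a different cross
  cells <- simulate_cells(outside, NULL,
                          observation_params(breadth = 0.05,
                                             doublet_rate = 0), seed = 35)
  post <- suppressWarnings(
    posterior_genotypes(cells$allele_counts, fx$map,
                        hmm_params(site_freq = colMeans(fx$panel)),
                        barcodes = cells$truth$barcode))
  res <- assign_cells(post, fx$panel, n_null = 100, fdr = 0.05, seed = 36)
  # realized false-assignment proportion at most nominal (binomial slack)
  n <- nrow(res)
  expect_lte(sum(res$assigned), qbinom(0.99, n, 0.05))
})

test_that("assignment recovers true strains on simulated cells", {
  fx <- assign_fixture()
  tr <- fx$cells$truth
  post <- suppressWarnings(
    posterior_genotypes(fx$cells$allele_counts, fx$map,
                        hmm_params(site_freq = colMeans(fx$panel)),
                        barcodes = tr$barcode))
  res <- assign_cells(post, fx$panel, n_null = 100,
                      counts = fx$cells$allele_counts, seed = 37)
  ok <- res$assigned & !tr$is_doublet
  expect_gt(sum(ok), 0.8 * sum(!tr$is_doublet))
  expect_gt(mean(res$strain[ok] == tr$strain[ok]), 0.95)
  # doublet and assigned flags are mutually exclusive
  expect_false(any(res$doublet & res$assigned))
})

test_that("the doublet rule requires all three clauses", {
  fx <- mapping_fixture()
  cells <- simulate_cells(fx$panel, NULL,
                          observation_params(breadth = 0.08,
                                             doublet_rate = 0.15),
                          seed = 38)
  tr <- cells$truth
  post <- suppressWarnings(
    posterior_genotypes(cells$allele_counts, fx$map,
                        hmm_params(site_freq = colMeans(fx$panel)),
                        barcodes = tr$barcode))
  res <- assign_cells(post, fx$panel, n_null = 50,
                      counts = cells$allele_counts, seed = 39)
  # constructed 50:50 mixtures at elevated coverage are flagged
  expect_gt(mean(res$doublet[tr$is_doublet]), 0.8)
  expect_lt(mean(res$doublet[!tr$is_doublet]), 0.05)
  # clause 1: a low-coverage cell is never flagged, whatever its fit
  cov <- table(cells$allele_counts$barcode)
  lowcov <- names(cov)[cov < quantile(cov, 0.75)]
  expect_false(any(res$doublet[res$barcode %in% lowcov]))
  # clause 3: a misfitting high-coverage cell whose top two matches are
  # near-identical strains is not flagged; with unrelated top strains it is
  withr::with_seed(41, {
    sA <- rbinom(400, 1, 0.5)
    sB <- sA; sB[1:8] <- 1 - sB[1:8]          # near-copy of sA
    sC <- rbinom(400, 1, 0.5)                 # unrelated
    panel3 <- rbind(sA = sA, sB = sB, sC = sC)
    reads <- rbinom(400, 1, 0.5)              # fits nothing in particular
    cnt3 <- tibble::tibble(barcode = "x", site = 1:400,
                           rm = as.integer(reads),
                           by = as.integer(1 - reads))
    base <- tibble::tibble(barcode = "x", strain = "sA", strain2 = "sB",
                           q = 1)
    expect_false(flag_doublets(base, cnt3, panel3, mismatch_rate = 0.05))
    base$strain2 <- "sC"
    expect_true(flag_doublets(base, cnt3, panel3, mismatch_rate = 0.05))
  })
})

test_that("consensus profiles take the posterior median and the deepest cell", {
  assignments <- tibble::tibble(
    barcode = c("a", "b", "c", "d"),
    strain = c("s1", "s1", "s1", "s2"),
    assigned = c(TRUE, TRUE, TRUE, FALSE))
  post <- rbind(a = c(0.1, 1), b = c(0.9, 1), c = c(0.95, 0), d = c(0.5, 0.5))
  colnames(post) <- c("1", "2")
  umi <- matrix(c(5, 0, 9, 1, 2, 2, 7, 7), nrow = 2,
                dimnames = list(c("g1", "g2"), c("a", "b", "c", "d")))
  cons <- consensus_profiles(assignments, post, umi)
  expect_equal(rownames(cons$genotype), "s1")  # s2 has no assigned cells
  expect_equal(unname(cons$genotype["s1", ]), c(0.9, 1))
  expect_equal(cons$strains$consensus_cell, "b")  # largest total UMI
  expect_equal(unname(cons$expression[, "s1"]), c(9, 1))
  # a single assigned cell is its own consensus
  one <- consensus_profiles(assignments[1, ], post, umi)
  expect_equal(unname(one$genotype["s1", ]), unname(post["a", ]))
})

test_that("consensus genotypes relate to truth better than single cells", {
  fx <- dense_fixture()
  tr <- fx$cells$truth
  post <- suppressWarnings(
    posterior_genotypes(fx$cells$allele_counts, fx$map,
                        hmm_params(site_freq = colMeans(fx$panel)),
                        barcodes = tr$barcode))
  # use the truth assignment so the comparison isolates the consensus step
  assignments <- tibble::tibble(barcode = tr$barcode, strain = tr$strain,
                                assigned = !tr$is_doublet)
  cons <- consensus_profiles(assignments, post)
  cell_r2 <- vapply(which(!tr$is_doublet), function(i) {
    suppressWarnings(as.numeric(relatedness(post$prob[i, ],
                                            fx$panel[tr$strain[i], ])))
  }, numeric(1))
  cons_r2 <- vapply(rownames(cons$genotype), function(s) {
    suppressWarnings(as.numeric(relatedness(cons$genotype[s, ],
                                            fx$panel[s, ])))
  }, numeric(1))
  expect_gt(median(cons_r2), median(cell_r2))
})

test_that("expression normalization standardizes genes then scales by totals", {
  m <- matrix(c(10, 0, 4, 2, 6, 1), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  norm <- normalize_expression(m)
  z <- t(scale(t(m)))
  expected <- t(sweep(z, 2, colSums(m), "/"))
  expect_equal(norm, expected)
  mm <- rbind(m, g4 = c(1, 1))
  expect_message(n2 <- normalize_expression(mm), "zero-variance")
  expect_equal(ncol(n2), 3)
})

test_that("the expression pre-transform hook is identity by default and smooths at low rank", {
  withr::with_seed(99, {
    base <- tcrossprod(matrix(rnorm(40 * 3), 40), matrix(rnorm(25 * 3), 25))
    noisy <- base + matrix(rnorm(40 * 25, 0, 0.5), 40)
    expect_identical(smooth_expression(noisy), noisy)
    sm <- smooth_expression(noisy, "low_rank", rank = 3)
    expect_lt(mean((sm - base)^2), mean((noisy - base)^2))
    expect_equal(dim(sm), dim(noisy))
  })
})
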