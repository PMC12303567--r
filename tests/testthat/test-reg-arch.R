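make_eqtl_tbl <- function(sites, genes, betas = NULL) {
  tibble::tibble(gene = genes, site = sites,
                 beta = betas %||% rep(1, length(sites)))
}

test_that("hotspot windows follow the top-quartile rule", {
  map <- genetic_map(data.frame(chrom = "c1", pos = c(5000L, 30000L, 60000L,
                                                      90000L, 120000L),
                                cm = 0:4 * 10))
  # all eQTL in one window: unique hotspot
  e1 <- make_eqtl_tbl(rep(1L, 6), paste0("g", 1:6))
  h1 <- find_hotspots(e1, map)
  expect_equal(sum(h1$hotspot), 1)
  expect_equal(h1$start[h1$hotspot], 1L)
  # one eQTL per window: degenerate constant distribution, all flagged
  e2 <- make_eqtl_tbl(1:5, paste0("g", 1:5))
  h2 <- find_hotspots(e2, map)
  expect_true(all(h2$hotspot[h2$n_eqtl > 0]))
  # windows tile from position 1 in non-overlapping 25-kb bins
  expect_true(all(h2$end - h2$start == 24999L))
  expect_false(any(duplicated(h2[c("chrom", "start")])))
})

test_that("hotspot flags are invariant to chromosome relabelling", {
  withr::with_seed(71, {
    map <- sim_genetic_map(n_sites = 150, n_chrom = 3, seed = 72)
    e <- make_eqtl_tbl(sample.int(150, 60, replace = TRUE),
                       sample(paste0("g", 1:25), 60, replace = TRUE))
    h <- find_hotspots(e, map)
    relabel <- c(chr01 = "chrZ", chr02 = "chrY", chr03 = "chrX")
    map2 <- map
    map2$chrom <- unname(relabel[map2$chrom])
    map2 <- genetic_map(dplyr::arrange(map2[c("chrom", "pos", "cm")],
                                       chrom, pos))
    # remap site ids to the re-sorted map
    key <- paste(unname(relabel[map$chrom]), map$pos)
    e2 <- e
    e2$site <- map2$site[match(key[e$site], paste(map2$chrom, map2$pos))]
    h2 <- find_hotspots(e2, map2)
    m1 <- h1_key <- paste(unname(relabel[h$chrom]), h$start)
    m2 <- paste(h2$chrom, h2$start)
    expect_equal(h$hotspot[order(m1)], h2$hotspot[order(m2)])
  })
})

test_that("cis/trans classification is strand-aware and total", {
  map <- genetic_map(data.frame(
    chrom = c("c1", "c1", "c1", "c2"),
    pos = c(500L, 4500L, 9850L, 500L),
    cm = c(0, 2, 4, 0)))
  genes <- tibble::tibble(
    gene = c("plus", "minus"),
    chrom = "c1",
    start = c(1000L, 6000L),
    end = c(3000L, 9700L),
    strand = c("+", "-"))
  e <- make_eqtl_tbl(c(1L, 3L, 4L, 2L), c("plus", "minus", "plus", "ghost"))
  expect_warning(lab <- classify_cis_trans(e, genes, map), "absent")
  expect_equal(lab$type[1], "cis")    # 500 bp upstream of plus-strand TSS
  expect_equal(lab$type[2], "cis")    # 150 bp past the 3' end, minus strand
  expect_equal(lab$type[3], "trans")  # different chromosome
  expect_equal(lab$type[4], "trans")  # unannotated gene
  expect_false(anyNA(lab$type))
})

test_that("alignment matches brute force over all monotone pairings", {
  withr::with_seed(73, {
    for (rep in 1:30) {
      nq <- sample(1:6, 1); ne <- sample(1:6, 1)
      S <- matrix(runif(nq * ne), nq, ne)
      S[matrix(runif(nq * ne) < 0.3, nq, ne)] <- 0
      gp <- runif(1, 0, 1)
      al <- cellcross:::align_loci(S, gp)
      expect_equal(al$score, brute_align_score(S, gp), tolerance = 1e-10)
      # each locus appears in at most one pair, pairs are monotone
      if (nrow(al$pairs) > 1) {
        expect_true(all(diff(al$pairs[, 1]) > 0))
        expect_true(all(diff(al$pairs[, 2]) > 0))
      }
      # the reported score decomposes into pairs minus gaps
      expect_equal(al$score,
                   sum(S[al$pairs]) - gp * (nq - nrow(al$pairs)),
                   tolerance = 1e-10)
    }
  })
})

test_that("matching refits QTL effects and respects distance decay", {
  withr::with_seed(74, {
    map <- sim_genetic_map(n_sites = 120, n_chrom = 4, seed = 75)
    panel <- simulate_cross(map, 200, seed = 76)
    qtl_sites <- c(10L, 50L, 95L)
    y_expr <- drop(scale(panel[, qtl_sites]) %*% c(1, -0.7, 0.5)) +
      rnorm(200, 0, 0.3)
    qtl <- cellcross:::new_qtl_fit(qtl_sites, c(1, -0.7, 0.5), 0, 1, log(200),
                                   10, 200)
    # identical eQTL sites and effects: perfect diagonal pairing, score 1 each
    eq <- tibble::tibble(site = qtl_sites, beta = c(1, -0.7, 0.5))
    m <- match_qtl_eqtl(qtl, y_expr, panel, map, eq, tau = 1)
    expect_equal(nrow(m$pairs), 3)
    expect_equal(m$pairs$qtl_site, qtl_sites)
    expect_gt(min(m$pairs$score), 0.8)
    # an eQTL far away on the same chromosome is left unmatched
    far <- map$site[map$chrom == map$chrom[10]]
    far <- far[which.max(abs(map$cm[far] - map$cm[10]))]
    eq2 <- tibble::tibble(site = far, beta = 1)
    qtl1 <- cellcross:::new_qtl_fit(10L, 1, 0, 1, log(200), 10, 200)
    m2 <- match_qtl_eqtl(qtl1, y_expr, panel, map, eq2, delta = 1,
                         gap_penalty = 0.5)
    expect_equal(nrow(m2$pairs), 0)
    expect_equal(m2$unmatched_qtl, 10L)
    expect_equal(m2$score, -0.5)
    # empty eQTL model: everything unmatched at the stated score
    m3 <- match_qtl_eqtl(qtl, y_expr, panel, map,
                         tibble::tibble(site = integer(0), beta = numeric(0)))
    expect_equal(m3$score, -0.5 * 3)
  })
})

test_that("rank permutation test honours its extreme cases and null", {
  # matched set holds the top ranks: no subset can beat it
  expect_equal(rank_permutation_test(c(9, 10), c(1:8), seed = 1), 0)
  expect_equal(rank_permutation_test(c(9, 10), c(1:8), seed = 1,
                                     add_one = TRUE), 1 / 1000)
  # single worse-ranked matched QTL: p = 1
  expect_equal(rank_permutation_test(1, 2, n_perm = 99, seed = 1), 1)
  expect_warning(p0 <- rank_permutation_test(1, numeric(0)), "undefined")
  expect_true(is.na(p0))
  expect_error(rank_permutation_test(c(1, 2), 3), "larger")
  # uniform p-values under a random matched set
  withr::with_seed(77, {
    ranks <- 1:30
    pv <- replicate(300, {
      m <- sample(ranks, 5)
      rank_permutation_test(m, setdiff(ranks, m), n_perm = 199,
                            seed = sample.int(1e6, 1))
    })
    expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
  })
})

test_that("model similarity is 1 for self, 0 across chromosomes, e^-1 at one decay length", {
  map <- genetic_map(data.frame(
    chrom = rep(c("c1", "c2"), each = 30),
    pos = rep(seq_len(30) * 10000L, 2),
    cm = rep(seq_len(30) * 5, 2)))
  panel <- matrix(0.5, nrow = 4, ncol = 60,
                  dimnames = list(paste0("s", 1:4), NULL))  # flat frequencies
  ma <- cellcross:::new_qtl_fit(c(2L, 8L, 14L), c(1, 1, 1), 0, 1, 1, 10, 100)
  mb <- cellcross:::new_qtl_fit(c(32L, 38L, 44L), c(1, 1, 1), 0, 1, 1, 10, 100)
  expect_equal(model_similarity(ma, ma, map, panel), 1)
  expect_equal(model_similarity(ma, mb, map, panel), 0)
  # every site shifted by exactly delta cM (2 map steps at 5 cM, delta = 10)
  mc <- cellcross:::new_qtl_fit(c(4L, 10L, 16L), c(1, 1, 1), 0, 1, 1, 10, 100)
  expect_equal(model_similarity(ma, mc, map, panel, delta = 10), exp(-1),
               tolerance = 1e-10)
  empty <- cellcross:::new_qtl_fit(integer(0), numeric(0), 0, 1, 1, 10, 100)
  expect_warning(s0 <- model_similarity(ma, empty, map, panel), "empty")
  expect_equal(s0, 0)
})

test_that("hotspot-QTL rank correlation behaves on concordant and discordant ranks", {
  map <- genetic_map(data.frame(chrom = "c1",
                                pos = (0:9) * 25000L + 100L,
                                cm = 0:9 * 10))
  # QTL in windows 1..5; regulated-gene counts concordant with |effect|
  hot <- find_hotspots(
    make_eqtl_tbl(rep(1:5, times = c(1, 2, 3, 4, 5)),
                  paste0("g", 1:15)), map)
  qtl <- cellcross:::new_qtl_fit(1:5, c(0.1, 0.2, 0.3, 0.4, 0.5), 0, 1, 1,
                                 10, 100)
  res <- hotspot_qtl_rank_correlation(qtl, hot, map)
  expect_equal(res$rho, 1)
  qtl_d <- cellcross:::new_qtl_fit(1:5, c(0.5, 0.4, 0.3, 0.2, 0.1), 0, 1, 1,
                                   10, 100)
  expect_equal(hotspot_qtl_rank_correlation(qtl_d, hot, map)$rho, -1)
  # QTL in empty windows are excluded; too few pairs is an error
  qtl_few <- cellcross:::new_qtl_fit(c(1L, 8L, 9L, 10L), rep(1, 4), 0, 1, 1,
                                     10, 100)
  expect_error(suppressMessages(
    hotspot_qtl_rank_correlation(qtl_few, hot, map)), "fewer than 3")
})

test_that("cis/trans effect comparison and odds helpers run on planted labels", {
  withr::with_seed(78, {
    eq <- tibble::tibble(
      gene = rep(paste0("g", 1:12), each = 2),
      beta = c(rbind(rnorm(12, 1.5, 0.2), rnorm(12, 0.5, 0.2))),
      type = rep(c("cis", "trans"), 12))
    res <- cis_trans_effect_test(eq)
    expect_equal(res$n_genes, 12)
    expect_lt(res$p_value, 0.05)
    expect_gt(res$median_cis, res$median_trans)
    expect_error(cis_trans_effect_test(eq[eq$type == "cis", ]), "both")
    orr <- odds_ratio_test(c(rep(TRUE, 20), rep(FALSE, 80)),
                           c(rep(TRUE, 15), rep(FALSE, 30), rep(TRUE, 5),
                             rep(FALSE, 50)))
    expect_gt(orr$odds_ratio, 1)
    expect_equal(orr$n11 + orr$n10 + orr$n01 + orr$n00, 100)
  })
})
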