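test_that("forward search handles the trivial limits", {
  withr::with_seed(61, {
    X <- matrix(rnorm(100 * 8), 100)
    y <- drop(X[, 3] * 2) + rnorm(100, 0, 0.5)
    # infinite penalty: empty model
    f_inf <- forward_search(X, y, lambda = 1e12)
    expect_equal(nrow(f_inf$sites), 0)
    expect_equal(f_inf$intercept, mean(y))
    # constant response: empty model
    f_const <- forward_search(X, rep(2, 100), lambda = 1)
    expect_equal(nrow(f_const$sites), 0)
    # strong single signal: exactly the causal column
    f1 <- forward_search(X, y, lambda = log(100))
    expect_true(3 %in% f1$sites$site)
  })
})

test_that("a strong planted site among orthogonalized predictors is found exactly", {
  withr::with_seed(62, {
    n <- 500
    X <- qr.Q(qr(matrix(rnorm(n * 100), n)))[, 1:100] * sqrt(n)
    y <- 5 * X[, 42] / sd(X[, 42]) + rnorm(n)
    fit <- forward_search(X, y, lambda = log(n))
    expect_equal(fit$sites$site[1], 42)
  })
})

test_that("the returned objective matches exhaustive best-subset search on orthogonalized designs", {
  withr::with_seed(63, {
    for (rep in 1:10) {
      n <- 200
      X <- qr.Q(qr(matrix(rnorm(n * 10), n))) * sqrt(n)
      beta <- rnorm(10) * rbinom(10, 1, 0.4)
      y <- drop(X %*% beta) + rnorm(n)
      lambda <- exp(runif(1, log(2), log(60)))
      fit <- forward_search(X, y, lambda)
      expect_equal(fit$objective, brute_best_subset(X, y, lambda),
                   tolerance = 1e-8)
    }
  })
})

test_that("the objective never increases along the search path", {
  withr::with_seed(64, {
    n <- 300; p <- 50
    X <- matrix(rbinom(n * p, 1, 0.5), n)
    y <- drop(scale(X[, c(5, 20, 33)]) %*% c(1, -0.8, 0.6)) + rnorm(n)
    fit <- forward_search(X, y, lambda = log(n))
    # each recorded drop exceeded lambda, so F_o decreased at every step
    expect_true(all(fit$drops > fit$lambda))
    # refitting the selected sites reproduces the reported RSS
    refit <- lm.fit(cbind(1, X[, fit$sites$site, drop = FALSE]), y)
    expect_equal(sum(refit$residuals^2), fit$rss, tolerance = 1e-8)
    expect_equal(fit$objective, fit$rss + fit$lambda * nrow(fit$sites))
  })
})

test_that("cross-validated lambda is deterministic and floors at log(n)", {
  withr::with_seed(65, {
    n <- 200
    X <- matrix(rbinom(n * 60, 1, 0.5), n)
    y <- drop(scale(X[, c(10, 40)]) %*% c(1.5, -1.2)) + rnorm(n)
    cv1 <- cv_lambda(X, y, seed = 7)
    cv2 <- cv_lambda(X, y, seed = 7)
    expect_identical(cv1, cv2)
    expect_gte(cv1$lambda, log(nrow(X) * 0.9) - 1e-9)
    expect_error(cv_lambda(X, y, n_folds = 1), "at least 2")
  })
})

test_that("cross-validation keeps null models near-empty and finds planted signal", {
  fx <- mapping_fixture()
  y <- fx$planted$fitness
  fit <- map_qtl(fx$panel, y, seed = 66)
  truth <- fx$planted$architecture$qtl$site
  hits <- vapply(truth, function(s) any(abs(fit$sites$site - s) <= 10),
                 logical(1))
  expect_gt(mean(hits), 0.7)
  # permuted fitness: almost nothing survives
  nulls <- vapply(1:5, function(i) {
    yp <- withr::with_seed(100 + i, sample(y))
    nrow(map_qtl(fx$panel, yp, seed = 100 + i)$sites)
  }, integer(1))
  expect_gte(mean(nulls <= 1), 0.6)
})

test_that("map_eqtl at the BIC penalty composes forward_search per gene", {
  fx <- mapping_fixture()
  expr <- fx$planted$expression[, 1:12]
  eset <- map_eqtl(fx$panel, expr, max_k = 6)
  expect_equal(eset$lambda, log(nrow(fx$panel)))
  Xs <- scale(fx$panel)
  for (g in c(1, 5, 9)) {
    direct <- forward_search(Xs, expr[, g], lambda = log(nrow(fx$panel)),
                             max_k = 6)
    expect_equal(eset$models[[colnames(expr)[g]]]$sites$site,
                 direct$sites$site)
    expect_equal(eset$models[[colnames(expr)[g]]]$rss, direct$rss)
  }
  expect_error(map_eqtl(fx$panel, expr, lambda = 1), "log\\(n\\)")
  # zero-variance genes are skipped with a message
  expr0 <- cbind(expr, flat = rep(1, nrow(expr)))
  expect_message(e0 <- map_eqtl(fx$panel, expr0, max_k = 6), "zero-variance")
  expect_false("flat" %in% names(e0$models))
})

test_that("per-gene eQTL scans find planted cis signals and stay sparse on nulls", {
  fx <- mapping_fixture()
  planted <- fx$planted$architecture$eqtl
  strong <- planted[abs(planted$beta) > 0.8, ]
  expr <- fx$planted$expression
  eset <- map_eqtl(fx$panel, expr[, unique(strong$gene), drop = FALSE],
                   max_k = 6)
  found <- vapply(unique(strong$gene), function(g) {
    sel <- eset$models[[g]]$sites$site
    any(vapply(strong$site[strong$gene == g],
               function(s) any(abs(sel - s) <= 10), logical(1)))
  }, logical(1))
  expect_gt(mean(found), 0.7)
  # null genes: hardly any selections at the BIC penalty (the floor
  # log(n) controls greedy selection when the locus count is modest)
  withr::with_seed(67, {
    null_expr <- matrix(rnorm(nrow(fx$panel) * 40), nrow(fx$panel))
    e0 <- map_eqtl(fx$panel[, seq_len(60)], null_expr, max_k = 6)
    expect_lte(mean(e0$summary$n_eqtl), 1)
  })
})

test_that("power analysis tables grow with sample size and are seed-stable", {
  fx <- mapping_fixture()
  genes <- fx$planted$architecture$eqtl$gene[
    abs(fx$planted$architecture$eqtl$beta) > 0.8][1:5]
  cols <- sort(unique(c(fx$planted$architecture$eqtl$site, seq_len(50))))
  geno <- fx$panel[, cols]
  pa <- power_analysis(geno, fx$planted$expression, genes = genes,
                       sizes = c(80, 300), n_reps = 2, seed = 68, max_k = 4)
  # score recovery of the planted eQTL at each size
  planted <- fx$planted$architecture$eqtl
  hit_rate <- vapply(split(pa$table, pa$table$size), function(d) {
    mean(mapply(function(g, sset) {
      sel <- cols[as.integer(strsplit(sset, ",")[[1]])]
      truth <- planted$site[planted$gene == g]
      length(sel) > 0 &&
        any(vapply(truth, function(s) any(abs(sel - s) <= 10), logical(1)))
    }, d$gene, d$sites))
  }, numeric(1))
  expect_gte(hit_rate[["300"]], hit_rate[["80"]])
  expect_true(all(c("slope", "r_squared") %in% names(pa$fits)))
  pa2 <- power_analysis(geno, fx$planted$expression, genes = genes,
                        sizes = c(80, 300), n_reps = 2, seed = 68, max_k = 4)
  expect_identical(pa$table, pa2$table)
  # single size: regression undefined but the table is still returned
  pa1 <- power_analysis(geno, fx$planted$expression, genes = genes,
                        sizes = 100, n_reps = 1, seed = 69, max_k = 4)
  expect_true(all(is.na(pa1$fits$slope)))
  expect_gt(nrow(pa1$table), 0)
})

test_that("qtl_fit tidiers and JSON round-trip preserve the model", {
  fx <- mapping_fixture()
  fit <- map_qtl(fx$panel, fx$planted$fitness, seed = 70)
  td <- tidy(fit, map = fx$map)
  expect_true(all(c("site", "beta", "chrom", "pos", "cm") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_loci, nrow(fit$sites))
  path <- withr::local_tempfile(fileext = ".json")
  write_qtl_json(fit, path)
  back <- read_qtl_json(path)
  expect_equal(back$sites$site, fit$sites$site)
  expect_equal(back$sites$beta, fit$sites$beta, tolerance = 1e-12)
  expect_equal(back$rss, fit$rss, tolerance = 1e-12)
})
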