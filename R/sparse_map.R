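#' L0-penalized stepwise forward search
#'
#' Greedy model search for the objective `F_o(beta) = RSS(beta) +
#' lambda * ||beta||_0`. Starting from the intercept-only model, each
#' iteration adds the locus whose inclusion minimizes the residual sum of
#' squares of the fully refit linear model (equivalently, maximizes the RSS
#' drop of the orthogonalized candidate), stopping when no addition lowers
#' `F_o` or when `max_k` loci are selected. Because the addition order
#' matters under linkage, an optional refinement pass after each addition
#' tries replacing every selected locus with every unselected one, accepting
#' strict RSS improvements, up to `refine_sweeps` sweeps. Ties are broken by
#' the lowest column index, so the search is deterministic.
#'
#' @param X Samples x loci numeric matrix.
#' @param y Response vector.
#' @param lambda Penalty per selected locus.
#' @param max_k Maximum model size (default `min(n / 10, 300)`).
#' @param refine Run the swap-refinement pass.
#' @param refine_sweeps Maximum refinement sweeps per addition.
#' @return An object of class `qtl_fit`; see [tidy.qtl_fit()].
#' @export
forward_search <- function(X, y, lambda, max_k = NULL, refine = TRUE,
                           refine_sweeps = 5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, n >= 3, all(is.finite(X)), lambda >= 0)
  if (is.null(max_k)) max_k <- max(1L, min(floor(n / 10), 300L))
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  if (rss0 == 0) {
    return(new_qtl_fit(integer(0), numeric(0), mean(y), rss0, lambda,
                       rss0, n, colnames(X)))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  cn2_orig <- colSums(Xc^2)
  tol_col <- max(cn2_orig) * 1e-10

  state <- fs_state(Xc, yc, integer(0))
  drops <- numeric(0)
  repeat {
    if (length(state$selected) >= max_k) break
    gains <- fs_gains(state, tol_col)
    j <- unname(which.max(gains))
    if (length(j) == 0 || !(gains[j] > lambda)) break
    drops <- c(drops, gains[j])
    state <- fs_add(state, j)
    if (refine) {
      ref <- fs_refine(Xc, yc, state$selected, state$rss, tol_col,
                       refine_sweeps)
      if (!identical(ref, state$selected)) {
        state <- fs_state(Xc, yc, ref)
      }
    }
  }
  sel <- state$selected
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, sel, drop = FALSE]), y)
  rss <- sum(fit$residuals^2)
  new_qtl_fit(sel, fit$coefficients[-1], fit$coefficients[1], rss, lambda,
              rss0, n, colnames(X), drops = drops)
}

# Search state: orthonormal basis of selected (centered) columns, residual,
# candidates projected onto the orthogonal complement.
fs_state <- function(Xc, yc, selected) {
  Zp <- Xc; cn2 <- colSums(Zp^2); r <- yc; rss <- sum(yc^2)
  Q <- matrix(0, nrow(Xc), 0)
  for (j in selected) {
    nq <- sqrt(cn2[j])
    q <- Zp[, j] / nq
    v <- drop(crossprod(Zp, q))
    Zp <- Zp - tcrossprod(q, v)
    cn2 <- pmax(cn2 - v^2, 0)
    pr <- sum(q * r)
    r <- r - q * pr
    rss <- rss - pr^2
    Q <- cbind(Q, q)
  }
  list(Zp = Zp, cn2 = cn2, r = r, rss = rss, selected = selected, Q = Q)
}

fs_gains <- function(state, tol_col) {
  g <- drop(crossprod(state$Zp, state$r))^2 / state$cn2
  g[state$cn2 < tol_col] <- -Inf
  g[state$selected] <- -Inf
  g
}

fs_add <- function(state, j) {
  nq <- sqrt(state$cn2[j])
  q <- state$Zp[, j] / nq
  v <- drop(crossprod(state$Zp, q))
  pr <- sum(q * state$r)
  list(Zp = state$Zp - tcrossprod(q, v),
       cn2 = pmax(state$cn2 - v^2, 0),
       r = state$r - q * pr,
       rss = state$rss - pr^2,
       selected = c(state$selected, j),
       Q = cbind(state$Q, q))
}

# Single-swap local search: replace each selected locus in turn by the best
# alternative if that strictly lowers the RSS at the same model size.
fs_refine <- function(Xc, yc, selected, rss_cur, tol_col, sweeps) {
  if (length(selected) < 1) return(selected)
  for (s in seq_len(sweeps)) {
    changed <- FALSE
    for (pos in seq_along(selected)) {
      base <- selected[-pos]
      st <- fs_state(Xc, yc, base)
      gains <- fs_gains(st, tol_col)
      j <- unname(which.max(gains))
      if (length(j) == 0 || !is.finite(gains[j])) next
      rss_new <- st$rss - gains[j]
      if (rss_new < rss_cur * (1 - 1e-12) - 1e-12) {
        selected[pos] <- j
        rss_cur <- rss_new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected
}

new_qtl_fit <- function(selected, beta, intercept, rss, lambda, rss0, n,
                        locus_names = NULL, drops = numeric(0)) {
  locus <- if (!is.null(locus_names)) locus_names[selected]
           else as.character(selected)
  structure(list(
    sites = tibble::tibble(site = selected, locus = locus,
                           order = seq_along(selected),
                           beta = unname(beta)),
    intercept = unname(intercept),
    rss = rss,
    lambda = lambda,
    objective = rss + lambda * length(selected),
    r2 = if (rss0 > 0) 1 - rss / rss0 else 0,
    n = n,
    drops = drops
  ), class = "qtl_fit")
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat("<qtl_fit> ", nrow(x$sites), " loci; RSS = ", signif(x$rss, 6),
      "; lambda = ", signif(x$lambda, 4),
      "; F_o = ", signif(x$objective, 6),
      "; R2 = ", round(x$r2, 4), "\n", sep = "")
  if (nrow(x$sites) > 0) print(x$sites, n = 10)
  invisible(x)
}

#' Predict from a forward-search model
#' @param object A `qtl_fit`.
#' @param newdata Samples x loci matrix with the same columns as the fit.
#' @param ... Unused.
#' @export
predict.qtl_fit <- function(object, newdata, ...) {
  sel <- object$sites$site
  drop(object$intercept +
         as.matrix(newdata)[, sel, drop = FALSE] %*% object$sites$beta)
}

#' Choose the L0 penalty by cross-validation
#'
#' Splits the samples into `n_folds` random partitions of similar size. For
#' each fold a forward-search path is fit on the remaining samples with the
#' penalty floored at `log(n_train)` (the BIC floor), and the held-out
#' prediction error of every model size along the path is measured on the
#' fold. The per-fold optimal lambda is the smallest penalty at or above the
#' floor whose greedy model minimizes the held-out error (ties resolved
#' toward the sparser model); `lambda*` is the mean of the per-fold optima.
#'
#' @param X Samples x loci matrix.
#' @param y Response.
#' @param n_folds Number of folds (default 10).
#' @param max_k_path Path length explored within each fold.
#' @param seed Integer seed controlling the partition.
#' @return List with `lambda` (the mean optimum), `floor` (`log(n)` for the
#'   full data) and `folds` (tibble: fold, size, lambda, mse).
#' @export
cv_lambda <- function(X, y, n_folds = 10, max_k_path = 50, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (n < n_folds) stop("need at least one sample per fold")
  fold_of <- withr::with_seed(seed, sample(rep(seq_len(n_folds),
                                               length.out = n)))
  per_fold <- lapply(seq_len(n_folds), function(f) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    floor_tr <- log(length(tr))
    path <- forward_search(X[tr, , drop = FALSE], y[tr], lambda = floor_tr,
                           max_k = max_k_path, refine = FALSE)
    sel <- path$sites$site
    drops <- path$drops
    K <- length(sel)
    sqerr <- matrix(0, K + 1, length(te))
    sqerr[1, ] <- (y[te] - mean(y[tr]))^2
    for (k in seq_len(K)) {
      cols <- sel[seq_len(k)]
      fit <- stats::lm.fit(cbind(1, X[tr, cols, drop = FALSE]), y[tr])
      pred <- drop(cbind(1, X[te, cols, drop = FALSE]) %*% fit$coefficients)
      sqerr[k + 1, ] <- (y[te] - pred)^2
    }
    mse <- rowMeans(sqerr)
    # representative lambda for each achievable greedy model size
    hi <- c(Inf, cummin(drops))              # hi[k+1] = min(drops[1..k])
    lo <- c(drops, 0)                        # lo[k+1] = drop[k+1] (0 past end)
    lam <- pmax(floor_tr, lo * (1 + 1e-9) + 1e-12)
    ok <- lam <= hi | seq_len(K + 1) == K + 1
    ok[K + 1] <- TRUE
    lam[K + 1] <- floor_tr
    cand <- which(ok)
    best <- cand[which.min(mse[cand])]
    # a sparser size whose held-out error is within one (paired) standard
    # error of the minimum is preferred: the error estimate cannot tell
    # the two apart, and the sparser model is the safer claim
    for (b in cand[cand < best]) {
      d <- sqerr[b, ] - sqerr[best, ]
      se_d <- stats::sd(d) / sqrt(length(d))
      if (mean(d) <= se_d) {
        best <- b
        break
      }
    }
    tibble::tibble(fold = f, size = best - 1L, lambda = lam[best],
                   mse = mse[best])
  })
  folds <- dplyr::bind_rows(per_fold)
  list(lambda = mean(folds$lambda), floor = log(n), folds = folds)
}

#' Map fitness QTL on a consensus panel
#'
#' Standardizes the genotype matrix, chooses the L0 penalty by
#' cross-validation ([cv_lambda()]) and fits the final forward-search model
#' on the full data at the chosen penalty, with refinement. Effect sizes
#' are therefore reported on standardized genotypes.
#'
#' @param genotype Strains x sites matrix of consensus genotypes.
#' @param fitness Fitness vector over the same strains.
#' @param n_folds,max_k_path,seed Passed to [cv_lambda()].
#' @param max_k Maximum model size for the final fit.
#' @return A `qtl_fit` with the cross-validation table attached as
#'   attributes `cv` and `lambda_floor`.
#' @export
map_qtl <- function(genotype, fitness, n_folds = 10, max_k_path = 50,
                    max_k = NULL, seed = 1) {
  stopifnot(nrow(genotype) == length(fitness))
  Xs <- standardize_columns_keep(genotype)
  cv <- cv_lambda(Xs$X, fitness, n_folds = n_folds, max_k_path = max_k_path,
                  seed = seed)
  lambda <- max(cv$lambda, cv$floor)
  fit <- forward_search(Xs$X, fitness, lambda = lambda, max_k = max_k,
                        refine = TRUE)
  fit$sites$site <- Xs$index[fit$sites$site]
  fit$sites$locus <- colnames(genotype)[fit$sites$site] %||%
    as.character(fit$sites$site)
  attr(fit, "cv") <- cv$folds
  attr(fit, "lambda_floor") <- cv$floor
  fit
}

# standardize but remember original column indices of retained columns
standardize_columns_keep <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 0 & !is.na(sds))
  if (length(keep) < ncol(X)) {
    message("dropping ", ncol(X) - length(keep),
            " zero-variance genotype column(s)")
  }
  list(X = scale(X[, keep, drop = FALSE]), index = unname(keep))
}

#' Map eQTL for every gene at the BIC penalty
#'
#' Runs [forward_search()] per gene at the fixed penalty
#' `lambda = log(n)` (the BIC choice; no cross-validation, which keeps the
#' per-gene scans fast and was found interchangeable with the
#' cross-validated penalty). Zero-variance genes are skipped with a message.
#'
#' @param genotype Strains x sites matrix (standardized internally).
#' @param expression Strains x genes matrix of responses (normalized
#'   consensus expression).
#' @param lambda Penalty; default `log(nrow(genotype))`.
#' @param max_k Maximum eQTL per gene.
#' @param refine Refinement switch passed through.
#' @return An object of class `eqtl_set`: list of per-gene `qtl_fit`s plus
#'   a `summary` tibble (gene, n_eqtl, r2).
#' @export
map_eqtl <- function(genotype, expression, lambda = NULL, max_k = 10,
                     refine = TRUE) {
  stopifnot(nrow(genotype) == nrow(expression))
  n <- nrow(genotype)
  if (is.null(lambda)) lambda <- log(n)
  if (lambda < log(n)) stop("lambda must be at least log(n)")
  Xs <- standardize_columns_keep(genotype)
  genes <- colnames(expression) %||% as.character(seq_len(ncol(expression)))
  models <- vector("list", ncol(expression))
  names(models) <- genes
  skipped <- character(0)
  for (j in seq_len(ncol(expression))) {
    yj <- expression[, j]
    if (stats::var(yj) == 0) {
      skipped <- c(skipped, genes[j])
      next
    }
    fit <- forward_search(Xs$X, yj, lambda = lambda, max_k = max_k,
                          refine = refine)
    fit$sites$site <- Xs$index[fit$sites$site]
    fit$sites$locus <- colnames(genotype)[fit$sites$site] %||%
      as.character(fit$sites$site)
    models[[j]] <- fit
  }
  if (length(skipped) > 0) {
    message("skipped ", length(skipped), " zero-variance gene(s)")
  }
  models <- models[!vapply(models, is.null, logical(1))]
  summary <- tibble::tibble(
    gene = names(models),
    n_eqtl = vapply(models, function(m) nrow(m$sites), integer(1)),
    r2 = vapply(models, function(m) m$r2, numeric(1))
  )
  structure(list(models = models, summary = summary, lambda = lambda, n = n),
            class = "eqtl_set")
}

#' @export
print.eqtl_set <- function(x, ...) {
  cat("<eqtl_set> ", length(x$models), " genes; lambda = ",
      signif(x$lambda, 4), "; median eQTL/gene = ",
      stats::median(x$summary$n_eqtl), "\n", sep = "")
  invisible(x)
}

#' Subsampling power analysis for eQTL detection
#'
#' Subsamples strains without replacement at each requested sample size,
#' re-runs the per-gene eQTL scan on a gene set, and records the number of
#' detected eQTL and model R-squared per gene. A per-gene linear regression
#' of the detected-eQTL count on sample size summarizes how power scales
#' with n (undefined, returned as NA, when only one size is requested).
#'
#' @param genotype Strains x sites matrix.
#' @param expression Strains x genes matrix.
#' @param genes Character vector of gene columns to scan (default: all).
#' @param sizes Sample sizes to test (each <= number of strains).
#' @param n_reps Subsampling replicates per size.
#' @param seed Integer seed.
#' @param ... Passed to [map_eqtl()].
#' @return List with `table` (tibble: size, rep, gene, n_eqtl, r2, and the
#'   selected sites as a comma-joined string) and `fits` (tibble: gene,
#'   slope, intercept, r_squared).
#' @export
power_analysis <- function(genotype, expression, genes = NULL,
                           sizes, n_reps = 3, seed = 1, ...) {
  n <- nrow(genotype)
  stopifnot(all(sizes <= n), all(sizes >= 3))
  if (is.null(genes)) {
    genes <- colnames(expression) %||% as.character(seq_len(ncol(expression)))
  }
  expr <- expression[, genes, drop = FALSE]
  rows <- withr::with_seed(seed, {
    out <- list()
    for (sz in sizes) {
      for (r in seq_len(n_reps)) {
        idx <- sample.int(n, sz)
        res <- map_eqtl(genotype[idx, , drop = FALSE],
                        expr[idx, , drop = FALSE], ...)
        smry <- dplyr::mutate(
          res$summary,
          sites = vapply(res$models[.data$gene], function(m) {
            paste(m$sites$site, collapse = ",")
          }, character(1)),
          size = sz, rep = r, .before = 1)
        out[[length(out) + 1]] <- smry
      }
    }
    dplyr::bind_rows(out)
  })
  fits <- if (length(unique(sizes)) > 1) {
    dplyr::group_modify(dplyr::group_by(rows, .data$gene), function(d, key) {
      m <- stats::lm(n_eqtl ~ size, data = d)
      ss_tot <- sum((d$n_eqtl - mean(d$n_eqtl))^2)
      r2 <- if (ss_tot > 0) 1 - sum(stats::resid(m)^2) / ss_tot else NA_real_
      tibble::tibble(slope = stats::coef(m)[["size"]],
                     intercept = stats::coef(m)[["(Intercept)"]],
                     r_squared = r2)
    })
  } else {
    tibble::tibble(gene = unique(rows$gene), slope = NA_real_,
                   intercept = NA_real_, r_squared = NA_real_)
  }
  list(table = rows, fits = dplyr::ungroup(fits))
}
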