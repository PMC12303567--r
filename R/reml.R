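#' Fit a Gaussian mixed model by restricted maximum likelihood
#'
#' Estimates variance components for `y = X beta + sum_c u_c + e` where each
#' random term `u_c` has covariance `sigma2_c * K_c`,
#' `K_c = W_c W_c' / m_c` is the genomic-relationship-style kernel of the
#' standardized design `W_c` (columns scaled to mean 0, variance 1;
#' zero-variance columns dropped with a message), and the residual has
#' covariance `sigma2_e * I`. The fixed design defaults to an intercept.
#' The fraction of variance explained by the model is reported as
#' `sum(sigma2_c) / (sum(sigma2_c) + sigma2_e)`.
#'
#' With a single random term the restricted likelihood is maximized exactly
#' by rotating into the eigenbasis of `K` and profiling the total variance,
#' leaving a one-dimensional search over the heritability ratio. With
#' several terms the fit uses expectation-maximization steps followed by
#' average-information (AI) Newton updates with step halving, constraining
#' components to be non-negative by projection at zero.
#'
#' @param y Response vector.
#' @param random Named list of random-effect design matrices (samples x
#'   predictors), or a single matrix.
#' @param X Fixed-effect design (default: intercept only).
#' @param se Compute standard errors from the AI (information) matrix.
#' @param max_iter,tol Convergence controls (relative restricted
#'   log-likelihood change).
#' @return An object of class `reml_fit` with elements `sigma2` (named,
#'   including `residual`), `varexp`, `loglik`, `se`, `n`, `iterations`,
#'   `converged` and `trajectory`.
#' @export
fit_reml <- function(y, random, X = NULL, se = TRUE,
                     max_iter = 200, tol = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.matrix(random)) random <- list(g = random)
  stopifnot(is.list(random), length(random) >= 1)
  if (is.null(names(random)) || any(names(random) == "")) {
    names(random) <- paste0("vc", seq_along(random))
  }
  if (is.null(X)) X <- matrix(1, n, 1)
  if (n <= ncol(X)) stop("need more samples than fixed effects")
  kernels <- lapply(random, function(W) {
    stopifnot(nrow(W) == n)
    W <- standardize_columns(W)
    tcrossprod(W) / ncol(W)
  })

  if (length(kernels) == 1) {
    fit <- reml_one_component(y, X, kernels[[1]], names(kernels))
  } else {
    fit <- reml_ai(y, X, kernels, max_iter = max_iter, tol = tol)
  }
  if (se) {
    fit$se <- reml_se(y, X, kernels, fit$sigma2)
  } else {
    fit$se <- rep(NA_real_, length(fit$sigma2))
    names(fit$se) <- names(fit$sigma2)
  }
  tot <- sum(fit$sigma2)
  fit$varexp <- if (tot > 0) sum(fit$sigma2[names(kernels)]) / tot else 0
  fit$n <- n
  class(fit) <- "reml_fit"
  fit
}

standardize_columns <- function(W) {
  W <- as.matrix(W)
  sds <- apply(W, 2, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (all(drop)) stop("random design has no variable columns")
  if (any(drop)) {
    message("dropping ", sum(drop), " zero-variance column(s) from a random design")
    W <- W[, !drop, drop = FALSE]
  }
  scale(W)
}

# Restricted log-likelihood at given variance components (dense, generic).
reml_loglik <- function(y, X, kernels, sigma2) {
  n <- length(y)
  V <- diag(sigma2[["residual"]], n)
  for (nm in names(kernels)) V <- V + sigma2[[nm]] * kernels[[nm]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  chX <- chol(XtViX)
  logdetX <- 2 * sum(log(diag(chX)))
  P <- Vi - Vi %*% X %*% chol2inv(chX) %*% crossprod(X, Vi)
  -0.5 * (logdetV + logdetX + drop(crossprod(y, P %*% y)))
}

# Exact single-component REML via eigendecomposition of K.
reml_one_component <- function(y, X, K, comp_name = "g") {
  eig <- eigen(K, symmetric = TRUE)
  prof <- reml_profile_1c(eig, y, X)
  opt <- stats::optimize(function(h) -prof(h), interval = c(0, 1 - 1e-9),
                         tol = 1e-10)
  # check the boundaries explicitly; optimize() can miss them
  cand <- c(opt$minimum, 1e-12, 1 - 1e-9)
  vals <- vapply(cand, prof, numeric(1))
  h <- cand[which.max(vals)]
  fit <- attr(prof(h), "fit")
  sigma2 <- stats::setNames(c(fit$s2 * h, fit$s2 * (1 - h)),
                            c(comp_name, "residual"))
  list(sigma2 = sigma2, loglik = fit$ll, iterations = 1L, converged = TRUE,
       trajectory = fit$ll)
}

# Profile restricted log-likelihood over the variance ratio h for a single
# kernel with eigendecomposition eig; total variance profiled out.
reml_profile_1c <- function(eig, y, X) {
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  n <- length(y); k <- ncol(X)
  function(h) {
    w <- h * d + (1 - h)            # V / s2 (diagonal in the eigenbasis)
    wi <- 1 / w
    XtWX <- crossprod(Xt, Xt * wi)
    chX <- chol(XtWX)
    beta <- backsolve(chX, forwardsolve(t(chX), crossprod(Xt, yt * wi)))
    r <- yt - Xt %*% beta
    quad <- sum(r^2 * wi)
    s2 <- quad / (n - k)
    ll <- -0.5 * (sum(log(w)) + 2 * sum(log(diag(chX))) +
                    (n - k) * log(s2) + (n - k))
    structure(ll, fit = list(s2 = s2, ll = ll))
  }
}

# Multi-component REML: EM-flavoured warm-up then average-information
# updates, with a line search so the restricted likelihood never decreases.
reml_ai <- function(y, X, kernels, max_iter = 200, tol = 1e-6) {
  n <- length(y)
  nc <- length(kernels)
  vy <- stats::var(y)
  if (vy == 0) stop("response has zero variance")
  sigma2 <- stats::setNames(rep(vy / (nc + 1), nc + 1),
                            c(names(kernels), "residual"))
  klist <- c(kernels, list(residual = diag(1, n)))
  floor_v <- vy * 1e-8

  eval_state <- function(sg) {
    V <- diag(sg[["residual"]], n)
    for (nm in names(kernels)) V <- V + sg[[nm]] * kernels[[nm]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    P <- Vi - Vi %*% X %*% chol2inv(chX) %*% crossprod(X, Vi)
    Py <- P %*% y
    list(ll = -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                        drop(crossprod(y, Py))),
         P = P, Py = Py)
  }

  cur <- eval_state(sigma2)
  if (is.null(cur)) stop("singular covariance at the starting values")
  traj <- cur$ll
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    PK <- lapply(klist, function(K) cur$P %*% K)
    score <- vapply(seq_along(klist), function(i) {
      -0.5 * (sum(diag(PK[[i]])) -
                drop(crossprod(cur$Py, klist[[i]] %*% cur$Py)))
    }, numeric(1))

    proposal <- if (iter <= 2) {
      # multiplicative fixed-point update: safe scale, keeps positivity
      vapply(seq_along(klist), function(i) {
        num <- drop(crossprod(cur$Py, klist[[i]] %*% cur$Py))
        den <- sum(diag(PK[[i]]))
        sigma2[[i]] * if (den > 0) num / den else 1
      }, numeric(1))
    } else {
      AI <- matrix(0, nc + 1, nc + 1)
      KPy <- lapply(klist, function(K) K %*% cur$Py)
      for (i in seq_along(klist)) {
        for (j in i:length(klist)) {
          AI[i, j] <- AI[j, i] <-
            0.5 * drop(crossprod(KPy[[i]], cur$P %*% KPy[[j]]))
        }
      }
      step <- tryCatch(solve(AI, score), error = function(e) score / diag(AI))
      sigma2 + step
    }

    # line search toward the proposal; constraint handling by projection
    accepted <- FALSE
    fac <- 1
    for (half in 1:10) {
      cand <- pmax(sigma2 + fac * (proposal - sigma2), floor_v)
      st <- eval_state(cand)
      if (!is.null(st) && st$ll >= traj[length(traj)] - 1e-10) {
        sigma2[] <- cand
        cur <- st
        accepted <- TRUE
        break
      }
      fac <- fac / 2
    }
    if (!accepted) {
      # no direction improves the likelihood: stationary point
      converged <- TRUE
      break
    }
    traj <- c(traj, cur$ll)
    k <- length(traj)
    if (k > 1 && abs(traj[k] - traj[k - 1]) /
          (abs(traj[k - 1]) + 1e-12) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(structure(class = c("reml_nonconvergence", "error", "condition"),
                   list(message = paste0("REML did not converge in ", max_iter,
                                         " iterations"),
                        call = sys.call(-1), trajectory = traj)))
  }
  list(sigma2 = sigma2, loglik = traj[length(traj)],
       iterations = length(traj), converged = converged, trajectory = traj)
}

# Standard errors from the inverse AI (observed information) matrix.
reml_se <- function(y, X, kernels, sigma2) {
  n <- length(y)
  klist <- c(kernels, list(residual = diag(1, n)))
  V <- diag(sigma2[["residual"]], n)
  for (nm in names(kernels)) V <- V + sigma2[[nm]] * kernels[[nm]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(stats::setNames(rep(NA_real_, length(sigma2)),
                                          names(sigma2)))
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  Py <- P %*% y
  AI <- matrix(0, length(klist), length(klist))
  KPy <- lapply(klist, function(K) K %*% Py)
  for (i in seq_along(klist)) {
    for (j in i:length(klist)) {
      AI[i, j] <- AI[j, i] <- 0.5 * drop(crossprod(KPy[[i]], P %*% KPy[[j]]))
    }
  }
  inv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_,
                                                        nrow(AI), ncol(AI)))
  stats::setNames(sqrt(pmax(diag(inv), 0)), names(sigma2))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> n =", x$n, "\n")
  comps <- data.frame(sigma2 = x$sigma2, se = x$se)
  print(round(comps, 5))
  cat("variance explained:", round(x$varexp, 4), "\n")
  invisible(x)
}

clip_renorm <- function(parts) {
  if (any(parts < 0)) {
    message("clipping negative variance fraction(s) to 0 and re-normalizing: ",
            paste(names(parts)[parts < 0], collapse = ", "))
    parts <- pmax(parts, 0)
    parts <- parts / sum(parts)
  }
  parts
}

#' Partition fitness variance into genotype, expression and shared parts
#'
#' Fits three mixed models by REML: genotype random effect only, expression
#' random effect only, and both jointly. With R_g, R_e and R_ge the
#' fractions of variance explained by the three models, the decomposition is
#' shared = R_g + R_e - R_ge, genotype-exclusive = R_ge - R_e,
#' expression-exclusive = R_ge - R_g, residual = 1 - R_ge. Small negative
#' components (possible through sampling noise) are clipped at zero and the
#' set re-normalized to sum to one.
#'
#' @param y Fitness vector over strains.
#' @param W_g Genotype design (strains x sites).
#' @param W_e Expression design (strains x genes), normalized.
#' @param component_names Labels used in the output.
#' @param ... Passed to [fit_reml()].
#' @return An object of class `variance_partition`: tibble with columns
#'   `component`, `fraction`, `se`, plus attributes `n` and `fits`.
#' @export
partition_fitness <- function(y, W_g, W_e,
                              component_names = c("genotype_exclusive",
                                                  "expression_exclusive",
                                                  "shared", "residual"),
                              ...) {
  fit_g <- fit_reml(y, list(g = W_g), ...)
  fit_e <- fit_reml(y, list(e = W_e), ...)
  fit_ge <- fit_reml(y, list(g = W_g, e = W_e), ...)
  r_g <- fit_g$varexp; r_e <- fit_e$varexp; r_ge <- fit_ge$varexp
  parts <- c(r_ge - r_e, r_ge - r_g, r_g + r_e - r_ge, 1 - r_ge)
  names(parts) <- component_names
  parts <- clip_renorm(parts)

  # delta-method SEs propagated from the per-fit varexp uncertainties
  se_fit <- function(f) {
    tot <- sum(f$sigma2)
    grad <- rep(-sum(f$sigma2[names(f$sigma2) != "residual"]) / tot^2,
                length(f$sigma2))
    grad[names(f$sigma2) != "residual"] <-
      grad[names(f$sigma2) != "residual"] + 1 / tot
    if (anyNA(f$se)) return(NA_real_)
    sqrt(drop(t(grad) %*% diag(f$se^2, length(grad)) %*% grad))
  }
  s_g <- se_fit(fit_g); s_e <- se_fit(fit_e); s_ge <- se_fit(fit_ge)
  ses <- c(sqrt(s_ge^2 + s_e^2), sqrt(s_ge^2 + s_g^2),
           sqrt(s_g^2 + s_e^2 + s_ge^2), s_ge)

  out <- tibble::tibble(component = names(parts),
                        fraction = unname(parts),
                        se = unname(ses))
  structure(out, n = length(y),
            fits = list(g = fit_g, e = fit_e, joint = fit_ge),
            class = c("variance_partition", class(out)))
}

#' Partition a gene's expression variance into cis and trans components
#'
#' Same difference algebra as [partition_fitness()] with the cis-eQTL and
#' trans-eQTL genotype designs as the two random terms. A gene with no
#' cis-eQTL has a cis fraction of exactly zero by definition (its variance
#' splits between the trans component and the residual); symmetrically for
#' a gene with no trans-eQTL.
#'
#' @param y Expression vector over strains.
#' @param W_cis Cis-eQTL genotype design (may be NULL or zero-column).
#' @param W_trans Trans-eQTL genotype design (may be NULL or zero-column).
#' @param ... Passed to [fit_reml()].
#' @return A `variance_partition` with components `cis_exclusive`,
#'   `trans_exclusive`, `shared`, `residual`.
#' @export
partition_cis_trans <- function(y, W_cis, W_trans, ...) {
  empty <- function(W) is.null(W) || ncol(as.matrix(W)) == 0
  if (empty(W_cis) && empty(W_trans)) {
    stop("both cis and trans designs are empty")
  }
  if (empty(W_cis) || empty(W_trans)) {
    nm <- if (empty(W_cis)) "trans" else "cis"
    W <- if (empty(W_cis)) W_trans else W_cis
    fit <- fit_reml(y, stats::setNames(list(W), nm), ...)
    parts <- tibble::tibble(
      component = c("cis_exclusive", "trans_exclusive", "shared", "residual"),
      fraction = c(if (nm == "cis") c(fit$varexp, 0) else c(0, fit$varexp),
                   0, 1 - fit$varexp),
      se = NA_real_
    )
    return(structure(parts, n = length(y), fits = list(single = fit),
                     class = c("variance_partition", class(parts))))
  }
  out <- partition_fitness(y, W_cis, W_trans,
                           component_names = c("cis_exclusive",
                                               "trans_exclusive",
                                               "shared", "residual"), ...)
  out
}

#' Expression heritability through principal-component weighting
#'
#' REML takes a single response vector, while expression is a matrix. The
#' expression matrix is therefore orthogonalized by PCA; the minimal set of
#' k leading PCs reaching `pc_var_threshold` of the total variance is each
#' fitted against the genotype random effect, and the overall expression
#' heritability is the eigenvalue-weighted sum
#' `sum_i (eigenvalue_i / total variance) * varexp(PC_i ~ genotype)`.
#' The eigenvalue share is taken against the total expression variance (not
#' re-normalized within the selected k), so with the threshold at 1 and
#' genotype fully determining expression the weighted sum reaches 1. Per-gene
#' heritabilities are fitted gene by gene against the same kernel.
#'
#' @param expression Strains x genes matrix (normalized).
#' @param W_g Genotype design (strains x sites).
#' @param pc_var_threshold Cumulative variance fraction the selected PCs
#'   must reach (default 0.99).
#' @param per_gene Also fit per-gene heritabilities.
#' @return An object of class `expression_heritability`: list with
#'   `overall`, `k`, `per_pc` (tibble: pc, eigenvalue, share, varexp) and
#'   `per_gene` (tibble or NULL).
#' @export
expression_heritability <- function(expression, W_g, pc_var_threshold = 0.99,
                                    per_gene = FALSE) {
  stopifnot(is.matrix(expression), nrow(expression) == nrow(W_g))
  n <- nrow(expression)
  pca <- stats::prcomp(expression, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  total <- sum(ev)
  share <- ev / total
  cum <- cumsum(share)
  k <- which(cum >= pc_var_threshold)[1]
  if (is.na(k)) k <- length(ev)
  if (k >= n - 1) {
    stop("threshold unattainable: it would require as many PCs as samples")
  }

  W <- standardize_columns(W_g)
  K <- tcrossprod(W) / ncol(W)
  eig <- eigen(K, symmetric = TRUE)
  X <- matrix(1, n, 1)
  pc_varexp <- vapply(seq_len(k), function(i) {
    prof <- reml_profile_1c(eig, pca$x[, i], X)
    opt <- stats::optimize(function(h) -prof(h), interval = c(0, 1 - 1e-9),
                           tol = 1e-10)
    cand <- c(opt$minimum, 1e-12, 1 - 1e-9)
    cand[which.max(vapply(cand, prof, numeric(1)))]
  }, numeric(1))
  overall <- sum(share[seq_len(k)] * pc_varexp)

  per_gene_tbl <- NULL
  if (per_gene) {
    g_h2 <- vapply(seq_len(ncol(expression)), function(j) {
      yj <- expression[, j]
      if (stats::var(yj) == 0) return(NA_real_)
      prof <- reml_profile_1c(eig, yj, X)
      opt <- stats::optimize(function(h) -prof(h), interval = c(0, 1 - 1e-9),
                             tol = 1e-10)
      cand <- c(opt$minimum, 1e-12, 1 - 1e-9)
      cand[which.max(vapply(cand, prof, numeric(1)))]
    }, numeric(1))
    per_gene_tbl <- tibble::tibble(
      gene = colnames(expression) %||% as.character(seq_len(ncol(expression))),
      h2 = g_h2
    )
  }
  structure(list(overall = overall, k = k,
                 per_pc = tibble::tibble(pc = seq_len(k),
                                         eigenvalue = ev[seq_len(k)],
                                         share = share[seq_len(k)],
                                         varexp = pc_varexp),
                 per_gene = per_gene_tbl, n = n),
            class = "expression_heritability")
}

#' @export
print.expression_heritability <- function(x, ...) {
  cat("<expression_heritability> overall =", round(x$overall, 4),
      "from", x$k, "PC(s) over", x$n, "strains\n")
  invisible(x)
}
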