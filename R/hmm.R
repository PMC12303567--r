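#' HMM parameters for single-cell genotype inference
#'
#' The genotype HMM has two hidden states per site (BY, RM) and three
#' parameter groups: a per-read sequencing/RT error rate, a per-read
#' index-swap rate (a swapped read comes from the pooled library, so its
#' allele is drawn from the pool RM frequency at the site), and transition
#' probabilities between adjacent sites derived from the genetic map through
#' the Haldane function, scaled by a single global recombination factor.
#'
#' @param error_rate Per-read error probability in \[0, 1\].
#' @param swap_rate Per-read index-swap probability in \[0, 1\].
#' @param rec_scale Global multiplier on map distances (1 = trust the map).
#' @param init_rm Initial state probability P(RM) at the left end of each
#'   chromosome (default 0.5, the F2 expectation).
#' @param site_freq Optional per-site pool RM frequencies; when NULL they
#'   are estimated from the pooled read counts at genotyping time.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(error_rate = 0.05, swap_rate = 0.05, rec_scale = 1,
                       init_rm = 0.5, site_freq = NULL) {
  p <- list(error_rate = error_rate, swap_rate = swap_rate,
            rec_scale = rec_scale, init_rm = init_rm, site_freq = site_freq)
  probs <- c(error_rate, swap_rate, init_rm)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (rec_scale < 0) stop("rec_scale must be non-negative")
  if (!is.null(site_freq) && any(site_freq < 0 | site_freq > 1)) {
    stop("site_freq must lie in [0, 1]")
  }
  class(p) <- "hmm_params"
  p
}

#' Log-probability of a site's reads given a hidden genotype state
#'
#' Each read independently reports the RM allele with probability
#' `(1 - s) * (1 - eps) + s * f` when the hidden state is RM and
#' `(1 - s) * eps + s * f` when it is BY, where `eps` is the error rate,
#' `s` the index-swap rate and `f` the pool RM frequency at the site.
#' Vectorized over sites.
#'
#' @param rm,by Read counts supporting the RM / BY allele.
#' @param state `"RM"` or `"BY"` (recycled).
#' @param error_rate,swap_rate,site_freq Channel parameters.
#' @return Log-probability of the observed counts given the state.
#' @export
emission_logprob <- function(rm, by, state, error_rate, swap_rate, site_freq) {
  stopifnot(all(rm >= 0), all(by >= 0),
            error_rate >= 0, error_rate <= 1,
            swap_rate >= 0, swap_rate <= 1)
  hit <- ifelse(state == "RM", 1 - error_rate, error_rate)
  p_rm <- (1 - swap_rate) * hit + swap_rate * site_freq
  ifelse(rm > 0, rm * log(p_rm), 0) + ifelse(by > 0, by * log1p(-p_rm), 0)
}

# Dense per-cell read-count matrices from the sparse triplet table.
counts_to_matrices <- function(counts, n_sites, barcodes = NULL) {
  if (is.null(barcodes)) barcodes <- sort(unique(counts$barcode))
  ci <- match(counts$barcode, barcodes)
  if (anyNA(ci)) stop("counts contain barcodes not in the barcode list")
  if (any(counts$site < 1 | counts$site > n_sites)) {
    stop("counts contain site indices outside the map")
  }
  rm_m <- matrix(0, nrow = length(barcodes), ncol = n_sites,
                 dimnames = list(barcodes, NULL))
  by_m <- rm_m
  rm_m[cbind(ci, counts$site)] <- counts$rm
  by_m[cbind(ci, counts$site)] <- counts$by
  list(rm = rm_m, by = by_m, barcodes = barcodes)
}

# Scaled emission likelihood matrices for one chromosome slice. Only
# covered entries (>= 1 read) differ from 1; the per-cell log scaling
# constants are accumulated into ll0.
emissions_chromosome <- function(rm, by, params, f) {
  n <- nrow(rm); len <- ncol(rm)
  eps <- params$error_rate; s <- params$swap_rate
  p_r <- pmin(pmax((1 - s) * (1 - eps) + s * f, 1e-300), 1 - 1e-12)
  p_b <- pmin(pmax((1 - s) * eps + s * f, 1e-300), 1 - 1e-12)
  e_rm <- matrix(1, n, len); e_by <- matrix(1, n, len)
  ll0 <- numeric(n)
  idx <- which(rm > 0 | by > 0)
  if (length(idx) > 0) {
    row <- ((idx - 1L) %% n) + 1L
    col <- ((idx - 1L) %/% n) + 1L
    l_rm <- rm[idx] * log(p_r[col]) + by[idx] * log1p(-p_r[col])
    l_by <- rm[idx] * log(p_b[col]) + by[idx] * log1p(-p_b[col])
    m <- pmax(l_rm, l_by)
    e_rm[idx] <- exp(l_rm - m)
    e_by[idx] <- exp(l_by - m)
    acc <- tapply(m, row, sum)
    ll0[as.integer(names(acc))] <- as.numeric(acc)
  }
  list(e_rm = e_rm, e_by = e_by, ll0 = ll0)
}

# Forward-backward over one chromosome, vectorized across cells (C core).
# rm, by: cells x sites matrices for this chromosome's sites (map order);
# r: recombination fractions for the len-1 intervals; returns posteriors,
# per-cell log-likelihood, and (optionally) E-step sufficient statistics.
fb_chromosome <- function(rm, by, r, params, f, want_suff = FALSE,
                          freq_chain = FALSE) {
  em <- emissions_chromosome(rm, by, params, f)
  core <- .fb_core(em$e_rm, em$e_by, as.numeric(r), params$init_rm,
                   as.numeric(f), freq_chain, want_suff)
  gamma <- core$gamma
  out <- list(gamma = gamma, loglik = core$loglik + em$ll0)
  if (want_suff) {
    out$suff <- list(
      rm_given_rm = colSums(gamma * rm),
      by_given_rm = colSums(gamma * by),
      rm_given_by = colSums((1 - gamma) * rm),
      by_given_by = colSums((1 - gamma) * by),
      switch = core$switch, stay = core$stay
    )
  }
  out
}

# Per-cell total log-likelihood of the data under given parameters
# (forward pass only).
hmm_loglik_matrices <- function(mats, map, params, f, freq_chain = FALSE) {
  r_all <- recomb_fraction(map, params$rec_scale)
  ll <- numeric(nrow(mats$rm))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    em <- emissions_chromosome(mats$rm[, idx, drop = FALSE],
                               mats$by[, idx, drop = FALSE], params, f[idx])
    ll <- ll + .fb_forward_ll(em$e_rm, em$e_by,
                              as.numeric(r_all[idx][-1]), params$init_rm,
                              as.numeric(f[idx]), freq_chain) +
      em$ll0
  }
  ll
}

pool_frequencies <- function(counts, n_sites) {
  f <- rep(0.5, n_sites)
  if (nrow(counts) > 0) {
    rm_tot <- tapply(counts$rm, counts$site, sum)
    tot <- tapply(counts$rm + counts$by, counts$site, sum)
    idx <- as.integer(names(tot))
    # add-half smoothing keeps swap emissions away from 0/1
    f[idx] <- (rm_tot + 0.5) / (tot + 1)
  }
  f
}

#' Posterior genotypes for every cell by forward-backward smoothing
#'
#' Runs the two-state HMM independently over each chromosome of each cell.
#' Sites without reads receive posteriors by propagation from flanking
#' covered sites through the recombination-derived transition probabilities,
#' which is what imputes genotypes at uncovered sites. Cells with no reads
#' at all get the flat prior everywhere (with a warning).
#'
#' @param counts Allele-count tibble (`barcode`, `site`, `rm`, `by`).
#' @param map The `genetic_map` defining site order and distances.
#' @param params An [hmm_params()].
#' @param barcodes Optional barcode universe (to include zero-read cells).
#' @return An object of class `cell_posteriors`: list with `prob`
#'   (cells x sites matrix of P(RM)), `loglik` (per-cell), `barcodes`, and
#'   the `map`.
#' @export
posterior_genotypes <- function(counts, map, params = hmm_params(),
                                barcodes = NULL) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  stopifnot(inherits(params, "hmm_params"))
  S <- nrow(map)
  mats <- counts_to_matrices(counts, S, barcodes)
  empty <- rowSums(mats$rm + mats$by) == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) have no reads; returning the flat prior")
  }
  f <- params$site_freq %||% pool_frequencies(counts, S)
  if (length(f) != S) stop("site_freq length must match the map")
  r_all <- recomb_fraction(map, params$rec_scale)
  prob <- matrix(NA_real_, nrow = length(mats$barcodes), ncol = S,
                 dimnames = list(mats$barcodes, map$site))
  ll <- numeric(length(mats$barcodes))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    res <- fb_chromosome(mats$rm[, idx, drop = FALSE],
                         mats$by[, idx, drop = FALSE],
                         r_all[idx][-1], params, f[idx])
    prob[, idx] <- res$gamma
    ll <- ll + res$loglik
  }
  structure(list(prob = prob, loglik = stats::setNames(ll, mats$barcodes),
                 barcodes = mats$barcodes, map = map, params = params),
            class = "cell_posteriors")
}

#' @export
print.cell_posteriors <- function(x, ...) {
  cat("<cell_posteriors> ", nrow(x$prob), " cells x ", ncol(x$prob),
      " sites; mean log-likelihood ", round(mean(x$loglik), 2), "\n", sep = "")
  invisible(x)
}

#' Estimate HMM parameters by Baum-Welch expectation-maximization
#'
#' Iterates forward-backward E-steps with M-steps that re-maximize the
#' expected complete-data log-likelihood over the error rate, the swap rate
#' and a single global recombination scale multiplying the map distances.
#' The total data log-likelihood is non-decreasing across iterations; the
#' loop stops at a relative change below `tol` or after `max_iter`
#' iterations.
#'
#' Two estimator details matter in practice. First, the error and swap
#' rates are separated only by how the mismatch rate varies with the pool
#' allele frequency across sites (at frequency 1/2 the two channels are
#' indistinguishable), so the pool frequencies should be as noise-free as
#' possible: when the reference `panel` is supplied its allele frequencies
#' are used; otherwise the empirical pooled read frequencies stand in, at
#' the cost of some feedback between their sampling noise and the apparent
#' mismatches. Second, doublet barcodes contribute reads from a second
#' genome that are state-independent and pool-distributed, i.e. exactly
#' swap-like; with `trim_alpha > 0` a second EM pass is run after dropping
#' cells whose posterior-weighted mismatch count significantly exceeds the
#' fitted channel rate (one-sided binomial test at that level). In addition,
#' because the cells are drawn from a finite panel, the realized per-site
#' state frequencies equal the panel allele frequencies rather than 1/2;
#' the estimation chain therefore recombines into the pool frequency
#' (P(recombine to RM) = r_i * f_i), which matches those marginals and keeps
#' the swap rate from absorbing them. Genotyping with
#' [posterior_genotypes()] keeps the symmetric chain. After EM, a short
#' simplex search on the exact likelihood (`polish`) resolves the nearly
#' flat direction trading the error rate against the swap rate.
#'
#' @param counts Allele-count tibble.
#' @param map The `genetic_map`.
#' @param init Starting [hmm_params()].
#' @param panel Optional reference genotype matrix supplying pool allele
#'   frequencies.
#' @param estimate Character subset of `c("error_rate", "swap_rate",
#'   "rec_scale")` to update; the others stay at their initial values.
#' @param trim_alpha Level of the per-cell misfit trim (0 disables the
#'   second pass).
#' @param max_iter,tol EM stopping controls.
#' @return An object of class `hmm_fit`: the fitted `params`, the
#'   log-likelihood `trajectory`, `iterations`, a `converged` flag and the
#'   number of `trimmed` cells.
#' @export
estimate_hmm <- function(counts, map, init = hmm_params(), panel = NULL,
                         estimate = c("error_rate", "swap_rate", "rec_scale"),
                         trim_alpha = 0.05, polish = FALSE,
                         max_iter = 200, tol = 1e-6) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  f <- init$site_freq %||%
    (if (!is.null(panel)) colMeans(panel) else pool_frequencies(counts,
                                                                nrow(map)))
  fit <- estimate_hmm_once(counts, map, init, f, estimate, max_iter, tol)
  fit$trimmed <- 0L
  use_counts <- counts
  if (trim_alpha > 0) {
    keep <- hmm_misfit_keep(counts, map, fit$params, trim_alpha)
    n_trim <- length(unique(counts$barcode)) - length(keep)
    if (n_trim > 0) {
      use_counts <- counts[counts$barcode %in% keep, , drop = FALSE]
      fit2 <- estimate_hmm_once(use_counts, map, fit$params, f, estimate,
                                max_iter, tol)
      fit2$trimmed <- n_trim
      fit <- fit2
    }
  }
  if (polish) fit <- hmm_polish(use_counts, map, fit, f, estimate)
  if (!is.null(panel) &&
      any(c("error_rate", "swap_rate") %in% estimate)) {
    fit$params <- refine_channel(counts, map, fit$params, panel,
                                 estimate = estimate)
  }
  fit
}

# Channel refinement against the reference panel: match each cell to its
# best panel strain, drop cells whose reads misfit it (residual doublets or
# misassignments), and fit (error, swap) by binomial maximum likelihood on
# the reads with the strain alleles taken as known. Conditioning on the
# states removes the near-degeneracy between the two rates that limits the
# latent-state likelihood.
refine_channel <- function(counts, map, params, panel, alpha = 0.01,
                           estimate = c("error_rate", "swap_rate"),
                           iterations = 3) {
  post <- suppressWarnings(posterior_genotypes(counts, map, params))
  D <- expected_distance_matrix(post$prob, panel)
  best <- apply(D, 1, which.min)
  allele <- panel[cbind(best[match(counts$barcode, rownames(post$prob))],
                        counts$site)]
  mis <- ifelse(allele >= 0.5, counts$by, counts$rm)
  tot <- counts$rm + counts$by
  f <- colMeans(panel)
  x <- ifelse(allele >= 0.5, 1 - f[counts$site], f[counts$site])
  mis_c <- tapply(mis, counts$barcode, sum)
  tot_c <- tapply(tot, counts$barcode, sum)
  # the filter anchor starts at the (doublet-robust) median mismatch
  # fraction and is re-derived from the fit on each iteration
  m0 <- stats::median(mis_c[tot_c > 0] / tot_c[tot_c > 0])
  est_e <- "error_rate" %in% estimate
  est_s <- "swap_rate" %in% estimate
  eps_hat <- params$error_rate
  s_hat <- params$swap_rate
  for (it in seq_len(iterations)) {
    pv <- stats::pbinom(ceiling(mis_c) - 1, tot_c, min(max(m0, 1e-6), 0.99),
                        lower.tail = FALSE)
    keep <- counts$barcode %in% names(pv)[pv >= alpha]
    # aggregate reads by (site, allele): the channel only depends on x
    key <- paste0(counts$site, "_", allele >= 0.5)[keep]
    agg_mis <- tapply(mis[keep], key, sum)
    agg_tot <- tapply(tot[keep], key, sum)
    agg_x <- tapply(x[keep], key, function(v) v[1])
    nll <- function(e, s) {
      p <- pmin(pmax((1 - s) * e + s * agg_x, 1e-9), 1 - 1e-9)
      -sum(agg_mis * log(p) + (agg_tot - agg_mis) * log1p(-p))
    }
    # the surface is nearly flat along the (e, s) trade-off; a nested
    # golden-section profile search is robust where quasi-Newton stalls
    prof <- function(s) {
      if (!est_e) return(nll(eps_hat, s))
      stats::optimize(function(e) nll(e, s), c(1e-6, 0.49), tol = 1e-8)$objective
    }
    if (est_s) {
      s_hat <- stats::optimize(prof, c(0, 0.9), tol = 1e-6)$minimum
    }
    if (est_e) {
      eps_hat <- stats::optimize(function(e) nll(e, s_hat), c(1e-6, 0.49),
                                 tol = 1e-8)$minimum
    }
    m0 <- (1 - s_hat) * eps_hat + s_hat / 2
  }
  params$error_rate <- eps_hat
  params$swap_rate <- s_hat
  params
}

# Direct maximization of the exact marginal likelihood from the EM
# solution. The EM surface is nearly flat along the direction trading the
# error rate against the swap rate (they are separated only by cross-site
# allele-frequency variation), where EM can stall; a short simplex search
# on the exact likelihood resolves the remaining ridge.
hmm_polish <- function(counts, map, fit, f, estimate, maxit = 150) {
  mats <- counts_to_matrices(counts, nrow(map))
  est_e <- "error_rate" %in% estimate
  est_s <- "swap_rate" %in% estimate
  est_r <- "rec_scale" %in% estimate
  p0 <- fit$params
  start <- c(if (est_e) stats::qlogis(min(max(p0$error_rate, 1e-4), 0.49)),
             if (est_s) stats::qlogis(min(max(p0$swap_rate, 1e-4), 0.89)),
             if (est_r) log(max(p0$rec_scale, 1e-3)))
  if (length(start) == 0) return(fit)
  mk <- function(th) {
    k <- 1
    p <- p0
    if (est_e) { p$error_rate <- stats::plogis(th[k]) * 0.5; k <- k + 1 }
    if (est_s) { p$swap_rate <- stats::plogis(th[k]) * 0.9; k <- k + 1 }
    if (est_r) p$rec_scale <- exp(th[k])
    p
  }
  # re-express the start on the scaled logistic parametrization
  start <- c(if (est_e) stats::qlogis(min(max(p0$error_rate / 0.5, 1e-6),
                                          1 - 1e-6)),
             if (est_s) stats::qlogis(min(max(p0$swap_rate / 0.9, 1e-6),
                                          1 - 1e-6)),
             if (est_r) log(max(p0$rec_scale, 1e-3)))
  nll <- function(th) -sum(hmm_loglik_matrices(mats, map, mk(th), f))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  fit$params <- mk(opt$par)
  fit$params$site_freq <- f
  fit$trajectory <- c(fit$trajectory, -opt$value)
  fit$loglik <- -opt$value
  fit
}

# cells whose reads are consistent with the fitted channel: one-sided
# binomial test of posterior-weighted mismatches vs the expected rate
hmm_misfit_keep <- function(counts, map, params, alpha) {
  post <- suppressWarnings(posterior_genotypes(counts, map, params))
  mats <- counts_to_matrices(counts, nrow(map))
  g <- post$prob[rownames(mats$rm), , drop = FALSE]
  mis <- rowSums(g * mats$by + (1 - g) * mats$rm)
  tot <- rowSums(mats$rm + mats$by)
  m0 <- (1 - params$swap_rate) * params$error_rate + params$swap_rate / 2
  m0 <- min(max(m0, 1e-6), 1 - 1e-6)
  p <- stats::pbinom(ceiling(mis) - 1, tot, m0, lower.tail = FALSE)
  rownames(mats$rm)[p >= alpha | tot == 0]
}

estimate_hmm_once <- function(counts, map, init, f, estimate, max_iter, tol) {
  stopifnot(inherits(init, "hmm_params"))
  estimate <- match.arg(estimate, c("error_rate", "swap_rate", "rec_scale"),
                        several.ok = TRUE)
  S <- nrow(map)
  if (nrow(counts) == 0) stop("no read counts supplied")
  covered_per_cell <- table(counts$barcode)
  if (!any(covered_per_cell >= 2)) {
    stop("need at least one cell with two or more covered sites")
  }
  tot_rm <- sum(counts$rm); tot_by <- sum(counts$by)
  degenerate <- tot_rm == 0 || tot_by == 0

  mats <- counts_to_matrices(counts, S)
  if (length(f) != S) stop("site_freq length must match the map")
  by_chrom <- split(seq_len(S), map$chrom)
  d_morgan <- lapply(by_chrom, function(idx) diff(map$cm[idx]) / 100)

  params <- init
  params$site_freq <- f
  traj <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    r_all <- recomb_fraction(map, params$rec_scale)
    ll <- 0
    nm_suff <- c("rm_given_rm", "by_given_rm", "rm_given_by", "by_given_by")
    suff <- stats::setNames(vector("list", 4), nm_suff)
    sw_list <- st_list <- vector("list", length(by_chrom))
    f_list <- vector("list", length(by_chrom))
    for (k in seq_along(by_chrom)) {
      idx <- by_chrom[[k]]
      res <- fb_chromosome(mats$rm[, idx, drop = FALSE],
                           mats$by[, idx, drop = FALSE],
                           r_all[idx][-1], params, f[idx], want_suff = TRUE)
      ll <- ll + sum(res$loglik)
      for (nm in nm_suff) suff[[nm]] <- c(suff[[nm]], res$suff[[nm]])
      sw_list[[k]] <- res$suff$switch
      st_list[[k]] <- res$suff$stay
      f_list[[k]] <- f[idx]
    }
    traj <- c(traj, ll)
    if (iter > 1) {
      rel <- abs(ll - traj[iter - 1]) / (abs(traj[iter - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }

    ## M-step: channel parameters (error, swap) --------------------------
    f_vec <- unlist(f_list)
    a1 <- suff$rm_given_rm; a2 <- suff$by_given_rm
    a3 <- suff$rm_given_by; a4 <- suff$by_given_by
    est_e <- "error_rate" %in% estimate
    est_s <- "swap_rate" %in% estimate
    if (est_e || est_s) {
      q_channel <- function(eps, s) {
        pr <- (1 - s) * (1 - eps) + s * f_vec
        pb <- (1 - s) * eps + s * f_vec
        pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
        pb <- pmin(pmax(pb, 1e-12), 1 - 1e-12)
        -sum(a1 * log(pr) + a2 * log1p(-pr) + a3 * log(pb) + a4 * log1p(-pb))
      }
      q_cur <- q_channel(params$error_rate, params$swap_rate)
      if (est_e && est_s) {
        opt <- stats::optim(c(min(max(params$error_rate, 1e-4), 0.45),
                              min(max(params$swap_rate, 1e-4), 0.85)),
                            function(th) q_channel(th[1], th[2]),
                            method = "L-BFGS-B",
                            lower = c(1e-6, 0), upper = c(0.49, 0.9))
        if (opt$value < q_cur) {
          params$error_rate <- opt$par[1]
          params$swap_rate <- opt$par[2]
        }
      } else if (est_e) {
        opt <- stats::optimize(function(e) q_channel(e, params$swap_rate),
                               c(1e-6, 0.49), tol = 1e-9)
        if (opt$objective < q_cur) params$error_rate <- opt$minimum
      } else {
        opt <- stats::optimize(function(sv) q_channel(params$error_rate, sv),
                               c(0, 0.9), tol = 1e-9)
        if (opt$objective < q_cur) params$swap_rate <- opt$minimum
      }
    }

    ## M-step: recombination scale --------------------------------------
    if ("rec_scale" %in% estimate) {
      sw <- unlist(sw_list); st <- unlist(st_list); dm <- unlist(d_morgan)
      keep <- dm > 0
      if (any(keep)) {
        q_rec <- function(logc) {
          r <- 0.5 * (1 - exp(-2 * exp(logc) * dm[keep]))
          r <- pmin(pmax(r, 1e-12), 0.5 - 1e-12)
          -sum(sw[keep] * log(r) + st[keep] * log1p(-r))
        }
        opt <- stats::optimize(q_rec, interval = log(c(1e-3, 1e3)))
        if (opt$objective < q_rec(log(max(params$rec_scale, 1e-3)))) {
          params$rec_scale <- exp(opt$minimum)
        }
      }
    }
  }
  if (degenerate) {
    warning("all reads support a single allele; estimates are at the boundary")
  }
  structure(list(params = params, trajectory = traj,
                 iterations = length(traj), converged = converged,
                 trimmed = 0L),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> error_rate = ", signif(x$params$error_rate, 4),
      ", swap_rate = ", signif(x$params$swap_rate, 4),
      ", rec_scale = ", signif(x$params$rec_scale, 4),
      "\n  ", x$iterations, " EM iterations; converged: ", x$converged,
      "\n", sep = "")
  invisible(x)
}

#' Raw majority-call genotypes from allele counts
#'
#' The pre-HMM genotype estimate: per covered site, the fraction of reads
#' supporting the RM allele; uncovered sites are NA. This is the baseline
#' the HMM posterior is compared against.
#'
#' @param counts Allele-count tibble.
#' @param n_sites Number of sites (map rows).
#' @param barcodes Optional barcode universe.
#' @return Cells x sites matrix of raw RM read fractions with NA where
#'   uncovered.
#' @export
raw_genotypes <- function(counts, n_sites, barcodes = NULL) {
  mats <- counts_to_matrices(counts, n_sites, barcodes)
  tot <- mats$rm + mats$by
  out <- mats$rm / tot
  out[tot == 0] <- NA_real_
  out
}
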