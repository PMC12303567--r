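# Independent reference implementations used to check the package's fast
# paths: exhaustive enumeration for the HMM and the alignment, best-subset
# search for the forward search, and a grid maximizer for REML.

# Exhaustive-path HMM: total log-likelihood and per-site posteriors of one
# chromosome by summing over all 2^S hidden paths.
brute_hmm <- function(rm, by, r, eps, s, f, pi_rm = 0.5) {
  S <- length(rm)
  p_r <- (1 - s) * (1 - eps) + s * f
  p_b <- (1 - s) * eps + s * f
  states <- as.matrix(expand.grid(rep(list(0:1), S)))
  lp <- apply(states, 1, function(st) {
    v <- log(ifelse(st[1] == 1, pi_rm, 1 - pi_rm))
    if (S > 1) {
      for (i in 2:S) {
        v <- v + log(ifelse(st[i] != st[i - 1], r[i - 1], 1 - r[i - 1]))
      }
    }
    for (i in seq_len(S)) {
      p <- if (st[i] == 1) p_r[i] else p_b[i]
      v <- v + rm[i] * log(p) + by[i] * log1p(-p)
    }
    v
  })
  m <- max(lp)
  ll <- m + log(sum(exp(lp - m)))
  w <- exp(lp - ll)
  list(loglik = ll, posterior = unname(colSums(states * w)))
}

# Best-subset search for the L0 objective over all subsets of p columns.
brute_best_subset <- function(X, y, lambda) {
  p <- ncol(X)
  yc <- y - mean(y)
  best <- sum(yc^2)
  for (m in seq_len(2^p) - 1) {
    sel <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    rss <- if (length(sel) == 0) sum(yc^2) else {
      sum(stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)$residuals^2)
    }
    best <- min(best, rss + lambda * length(sel))
  }
  best
}

# All monotone pairings of nq row-loci with ne column-loci, scored as the
# alignment does: sum of pair scores minus gap_penalty per unmatched row
# locus, pairs below min_score forbidden.
brute_align_score <- function(S, gap_penalty, min_score = exp(-3)) {
  nq <- nrow(S); ne <- ncol(S)
  best <- -Inf
  walk <- function(i, j, acc) {
    if (i > nq) {
      best <<- max(best, acc)
      return(invisible())
    }
    walk(i + 1, j, acc - gap_penalty)   # leave row locus i unmatched
    if (j <= ne) {
      for (jj in j:ne) {
        if (S[i, jj] >= min_score) walk(i + 1, jj + 1, acc + S[i, jj])
      }
    }
  }
  walk(1, 1, 0)
  best
}

# Restricted log-likelihood for a single kernel at variance components
# (s2g, s2e); used by the grid-search REML oracle.
reml_ll_1c <- function(y, K, s2g, s2e) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- s2g * K + diag(s2e, n)
  ch <- chol(V)
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  -0.5 * (2 * sum(log(diag(ch))) + log(XtViX[1, 1]) +
            drop(crossprod(y, P %*% y)))
}
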