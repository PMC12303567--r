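#' Tidy the eQTL of an `eqtl_set` into one row per (gene, site)
#'
#' @param x An `eqtl_set` from [map_eqtl()].
#' @param ... Unused.
#' @return Tibble with columns `gene`, `site`, `locus`, `order`, `beta`.
#' @export
tidy.eqtl_set <- function(x, ...) {
  rows <- purrr::imap(x$models, function(m, g) {
    dplyr::mutate(m$sites, gene = g, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene = character(), site = integer(),
                          locus = character(), order = integer(),
                          beta = numeric())
  }
  out
}

#' Locate eQTL hotspots in tiled genomic windows
#'
#' Tiles every chromosome from position 1 in non-overlapping windows of
#' `window_bp` base pairs and counts, per window, the eQTL falling in it and
#' the distinct genes they regulate. A window is flagged as a hotspot when
#' both counts are in the top quartile (at or above the third quartile) of
#' their distributions over occupied windows (windows with at least one
#' eQTL). With a constant count distribution every occupied window meets
#' the >= Q3 rule; that degenerate case is intentional.
#'
#' @param eqtl Tidy eQTL tibble (columns `gene`, `site`) such as
#'   `tidy(map_eqtl(...))`, or an `eqtl_set`.
#' @param map The `genetic_map` giving site coordinates.
#' @param window_bp Window size (default 25,000).
#' @return A tibble of class `hotspot_table`: `chrom`, `start`, `end`,
#'   `n_genes`, `n_eqtl`, `hotspot`.
#' @export
find_hotspots <- function(eqtl, map, window_bp = 25000) {
  if (inherits(eqtl, "eqtl_set")) eqtl <- tidy(eqtl)
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  loc <- dplyr::left_join(eqtl, map, by = "site")
  chrom_len <- tapply(map$pos, map$chrom, max)
  windows <- dplyr::bind_rows(lapply(names(chrom_len), function(ch) {
    n_win <- ceiling(chrom_len[[ch]] / window_bp)
    tibble::tibble(chrom = ch,
                   start = (seq_len(n_win) - 1L) * as.integer(window_bp) + 1L,
                   end = seq_len(n_win) * as.integer(window_bp))
  }))
  loc$win_start <- ((loc$pos - 1L) %/% as.integer(window_bp)) *
    as.integer(window_bp) + 1L
  counts <- dplyr::summarise(
    dplyr::group_by(loc, .data$chrom, .data$win_start),
    n_genes = dplyr::n_distinct(.data$gene),
    n_eqtl = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(windows, counts,
                          by = c("chrom", "start" = "win_start"))
  out$n_genes[is.na(out$n_genes)] <- 0L
  out$n_eqtl[is.na(out$n_eqtl)] <- 0L
  occupied <- out$n_eqtl >= 1
  if (any(occupied)) {
    q3_genes <- stats::quantile(out$n_genes[occupied], 0.75, names = FALSE)
    q3_eqtl <- stats::quantile(out$n_eqtl[occupied], 0.75, names = FALSE)
    out$hotspot <- occupied & out$n_genes >= q3_genes & out$n_eqtl >= q3_eqtl
  } else {
    out$hotspot <- FALSE
  }
  class(out) <- c("hotspot_table", class(out))
  out
}

#' Classify each eQTL as cis or trans
#'
#' An eQTL is cis to its gene when it lies on the same chromosome within the
#' strand-aware window from 1,000 bp upstream of the transcription start to
#' 200 bp downstream of the gene end; every other eQTL is trans. For a
#' plus-strand gene the window is `[start - 1000, end + 200]`; for a
#' minus-strand gene transcription starts at `end`, so the window is
#' `[start - 200, end + 1000]`. Genes missing from the annotation get all
#' their eQTL labelled trans, with a warning; genes without a strand default
#' to plus.
#'
#' @param eqtl Tidy eQTL tibble (`gene`, `site`) or an `eqtl_set`.
#' @param genes Gene annotation tibble: `gene`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param map The `genetic_map`.
#' @return The eQTL tibble with a `type` column in `{"cis", "trans"}`.
#' @export
classify_cis_trans <- function(eqtl, genes, map) {
  if (inherits(eqtl, "eqtl_set")) eqtl <- tidy(eqtl)
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$strand[is.na(genes$strand)] <- "+"
  ann <- dplyr::mutate(
    genes,
    win_lo = ifelse(.data$strand == "+", .data$start - 1000L,
                    .data$start - 200L),
    win_hi = ifelse(.data$strand == "+", .data$end + 200L,
                    .data$end + 1000L)
  )
  loc <- dplyr::left_join(eqtl, map[c("site", "chrom", "pos")], by = "site")
  merged <- dplyr::left_join(loc, ann[c("gene", "chrom", "win_lo", "win_hi")],
                             by = "gene", suffix = c("", ".gene"))
  missing <- is.na(merged$chrom.gene)
  if (any(missing)) {
    warning(sum(missing), " eQTL belong to genes absent from the annotation; ",
            "labelled trans")
  }
  cis <- !missing &
    merged$chrom == merged$chrom.gene &
    merged$pos >= merged$win_lo & merged$pos <= merged$win_hi
  out <- eqtl
  out$type <- ifelse(cis, "cis", "trans")
  out
}

# Pair score between two loci: exponential decay in genetic distance and in
# effect-size difference, optionally in allele-frequency difference; zero
# across chromosomes.
pair_scores <- function(chrom_a, cm_a, beta_a, chrom_b, cm_b, beta_b,
                        delta = 10, tau = NULL, freq_a = NULL, freq_b = NULL,
                        phi = 0.1) {
  if (is.null(tau)) {
    tau <- stats::sd(c(beta_a, beta_b))
    if (!is.finite(tau) || tau == 0) tau <- 1
  }
  S <- exp(-abs(outer(cm_a, cm_b, "-")) / delta) *
    exp(-abs(outer(beta_a, beta_b, "-")) / tau)
  if (!is.null(freq_a)) {
    S <- S * exp(-abs(outer(freq_a, freq_b, "-")) / phi)
  }
  S[outer(chrom_a, chrom_b, "!=")] <- 0
  S
}

# Global alignment of two position-sorted locus lists. Matches must be
# order-preserving; an unmatched row-locus (QTL) costs gap_penalty, an
# unmatched column-locus (eQTL) is free. Pairs scoring below min_score
# (default exp(-3), about three decay lengths of the distance kernel) are
# never formed: such a pairing carries no evidence of identity even though
# its score is positive. Returns the optimal score and the matched pairs.
align_loci <- function(S, gap_penalty, min_score = exp(-3)) {
  nq <- nrow(S); ne <- ncol(S)
  M <- matrix(0, nq + 1, ne + 1)
  M[, 1] <- -gap_penalty * (0:nq)
  # first row stays 0: skipping eQTL is free
  ptr <- matrix(0L, nq + 1, ne + 1)  # 1 = diag, 2 = up (gap QTL), 3 = left
  ptr[2:(nq + 1), 1] <- 2L
  if (ne > 0) ptr[1, 2:(ne + 1)] <- 3L
  for (i in seq_len(nq)) {
    for (j in seq_len(ne)) {
      diag_s <- if (S[i, j] >= min_score) M[i, j] + S[i, j] else -Inf
      cand <- c(diag_s, M[i, j + 1] - gap_penalty, M[i + 1, j])
      best <- which.max(cand)
      M[i + 1, j + 1] <- cand[best]
      ptr[i + 1, j + 1] <- best
    }
  }
  pairs <- list()
  i <- nq + 1; j <- ne + 1
  while (i > 1 || j > 1) {
    mv <- ptr[i, j]
    if (mv == 1L) {
      pairs[[length(pairs) + 1]] <- c(i - 1L, j - 1L)
      i <- i - 1; j <- j - 1
    } else if (mv == 2L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  pairs <- if (length(pairs) > 0) {
    do.call(rbind, rev(pairs))
  } else matrix(integer(0), ncol = 2)
  list(score = M[nq + 1, ne + 1], pairs = pairs)
}

#' Match fitness QTL to a gene's eQTL by global alignment
#'
#' Predicted expression effects at the QTL positions are obtained by
#' multiple regression of the gene's expression on the QTL genotypes. Each
#' same-chromosome (QTL, eQTL) pair is scored
#' `exp(-d_cM / delta) * exp(-|beta_hat_q - beta_e| / tau)` (zero across
#' chromosomes), and the score-maximal order-preserving pairing over the two
#' position-sorted lists is found by Needleman-Wunsch global alignment with
#' a gap penalty per unmatched QTL (unmatched eQTL are free).
#'
#' @param qtl A `qtl_fit` for the fitness trait.
#' @param expression Expression vector of the gene over strains.
#' @param genotype Strains x sites genotype matrix (same columns as the
#'   map), used for the QTL-position regression.
#' @param map The `genetic_map`.
#' @param eqtl The gene's `qtl_fit` from the eQTL scan (or a tibble with
#'   `site` and `beta`).
#' @param delta Genetic-distance decay scale in cM.
#' @param tau Effect-size decay scale; default pooled SD of the effects.
#' @param gap_penalty Penalty per unmatched QTL.
#' @param min_score Minimum pair score for a match (default `exp(-3)`,
#'   about three decay lengths); weaker pairs are left unmatched.
#' @return An object of class `match_result`: list with `pairs` (tibble:
#'   qtl_site, eqtl_site, score), `unmatched_qtl`, `score`.
#' @export
match_qtl_eqtl <- function(qtl, expression, genotype, map, eqtl,
                           delta = 10, tau = NULL, gap_penalty = 0.5,
                           min_score = exp(-3)) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  eqtl_sites <- if (inherits(eqtl, "qtl_fit")) eqtl$sites else eqtl
  qtl_sites <- qtl$sites$site
  if (length(qtl_sites) == 0) stop("the QTL model is empty")
  # refit QTL effects against the gene's expression
  Xq <- scale(as.matrix(genotype)[, qtl_sites, drop = FALSE])
  fit <- stats::lm.fit(cbind(1, Xq), as.numeric(expression))
  beta_q <- fit$coefficients[-1]
  ord_q <- order(qtl_sites)
  qs <- qtl_sites[ord_q]; bq <- unname(beta_q)[ord_q]
  if (nrow(eqtl_sites) == 0) {
    return(structure(list(
      pairs = tibble::tibble(qtl_site = integer(0), eqtl_site = integer(0),
                             score = numeric(0)),
      unmatched_qtl = qs,
      score = -gap_penalty * length(qs)), class = "match_result"))
  }
  ord_e <- order(eqtl_sites$site)
  es <- eqtl_sites$site[ord_e]; be <- eqtl_sites$beta[ord_e]
  S <- pair_scores(map$chrom[qs], map$cm[qs], bq,
                   map$chrom[es], map$cm[es], be,
                   delta = delta, tau = tau)
  al <- align_loci(S, gap_penalty, min_score)
  matched_q <- if (nrow(al$pairs) > 0) qs[al$pairs[, 1]] else integer(0)
  pairs <- tibble::tibble(
    qtl_site = matched_q,
    eqtl_site = if (nrow(al$pairs) > 0) es[al$pairs[, 2]] else integer(0),
    score = if (nrow(al$pairs) > 0) S[al$pairs] else numeric(0)
  )
  structure(list(pairs = pairs, unmatched_qtl = setdiff(qs, matched_q),
                 score = al$score), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " pair(s), ",
      length(x$unmatched_qtl), " unmatched QTL; score = ",
      signif(x$score, 5), "\n", sep = "")
  invisible(x)
}

#' Permutation test on the effect-size ranks of matched QTL
#'
#' Compares the average effect-size rank of a gene's matched QTL to the
#' average rank of `n_perm` random subsets of its unmatched QTL of the same
#' size. Ranks are positions in the ascending |effect| ordering of the full
#' QTL model (higher rank = larger effect), and the p-value is the
#' proportion of random subsets with a higher average rank than the matched
#' set; with `add_one = TRUE` the add-one convention
#' `(1 + #higher) / (1 + n_perm)` is used instead.
#'
#' @param matched_ranks Ranks of the matched QTL.
#' @param unmatched_ranks Ranks of the unmatched QTL.
#' @param n_perm Number of random subsets (default 999).
#' @param seed Integer seed.
#' @param add_one Use the add-one convention.
#' @return The p-value; NA (with a warning) when there are no unmatched QTL.
#' @export
rank_permutation_test <- function(matched_ranks, unmatched_ranks,
                                  n_perm = 999, seed = 1, add_one = FALSE) {
  m <- length(matched_ranks)
  if (length(unmatched_ranks) == 0) {
    warning("no unmatched QTL; p-value undefined")
    return(NA_real_)
  }
  if (m > length(unmatched_ranks)) {
    stop("matched set larger than the unmatched pool")
  }
  obs <- mean(matched_ranks)
  withr::with_seed(seed, {
    nu <- length(unmatched_ranks)
    means <- vapply(seq_len(n_perm), function(i) {
      mean(unmatched_ranks[sample.int(nu, m)])
    }, numeric(1))
    tol <- 1e-9 * (1 + abs(obs))
    higher <- sum(means > obs + tol) + 0.5 * sum(abs(means - obs) <= tol)
    if (add_one) (1 + higher) / (1 + n_perm) else higher / n_perm
  })
}

#' Similarity between two locus models
#'
#' Runs the same global alignment as [match_qtl_eqtl()] with the pair score
#' extended by an allele-frequency agreement factor
#' `exp(-|f_a - f_b| / phi)` (f = panel RM frequency at the site), and
#' normalizes the alignment score by the larger of the two self-scores, so
#' a model is always similar to itself at 1 and models on disjoint
#' chromosomes score 0.
#'
#' @param model_a,model_b `qtl_fit` objects.
#' @param map The `genetic_map`.
#' @param panel Strains x sites genotype matrix for allele frequencies.
#' @param delta,tau,phi,gap_penalty,min_score Scoring constants (see
#'   [match_qtl_eqtl()]).
#' @return Similarity in \[0, 1\].
#' @export
model_similarity <- function(model_a, model_b, map, panel,
                             delta = 10, tau = NULL, phi = 0.1,
                             gap_penalty = 0.5, min_score = exp(-3)) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  if (nrow(model_a$sites) == 0 || nrow(model_b$sites) == 0) {
    warning("empty model; similarity set to 0")
    return(0)
  }
  f <- colMeans(panel)
  if (is.null(tau)) {
    tau <- stats::sd(c(model_a$sites$beta, model_b$sites$beta))
    if (!is.finite(tau) || tau == 0) tau <- 1
  }
  score_of <- function(ma, mb) {
    sa <- ma$sites[order(ma$sites$site), ]
    sb <- mb$sites[order(mb$sites$site), ]
    S <- pair_scores(map$chrom[sa$site], map$cm[sa$site], sa$beta,
                     map$chrom[sb$site], map$cm[sb$site], sb$beta,
                     delta = delta, tau = tau,
                     freq_a = f[sa$site], freq_b = f[sb$site], phi = phi)
    align_loci(S, gap_penalty, min_score)$score
  }
  denom <- max(score_of(model_a, model_a), score_of(model_b, model_b))
  if (denom <= 0) return(0)
  max(score_of(model_a, model_b), 0) / denom
}

#' Rank correlation between QTL effects and hotspot activity
#'
#' Maps each QTL to its containing window, ranks QTL by absolute effect size
#' and windows by the number of genes they regulate, and reports the
#' Spearman correlation between the two rankings. QTL falling in windows
#' with no eQTL are excluded (with a message). The p-value uses the
#' large-sample approximation, or the exact permutation distribution below
#' 10 pairs.
#'
#' @param qtl A `qtl_fit`.
#' @param hotspots A `hotspot_table` from [find_hotspots()].
#' @param map The `genetic_map`.
#' @param window_bp Window size used to build the hotspot table.
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
hotspot_qtl_rank_correlation <- function(qtl, hotspots, map,
                                         window_bp = 25000) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  sites <- qtl$sites$site
  d <- tibble::tibble(
    site = sites,
    effect = abs(qtl$sites$beta),
    chrom = map$chrom[sites],
    start = ((map$pos[sites] - 1L) %/% as.integer(window_bp)) *
      as.integer(window_bp) + 1L
  )
  d <- dplyr::left_join(d, hotspots[c("chrom", "start", "n_genes", "n_eqtl")],
                        by = c("chrom", "start"))
  drop <- is.na(d$n_eqtl) | d$n_eqtl == 0
  if (any(drop)) {
    message(sum(drop), " QTL fall in windows without eQTL; excluded")
    d <- d[!drop, , drop = FALSE]
  }
  if (nrow(d) < 3) stop("fewer than 3 usable QTL-window pairs")
  ct <- suppressWarnings(
    stats::cor.test(d$effect, d$n_genes, method = "spearman",
                    exact = nrow(d) < 10)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' Paired comparison of cis- and trans-eQTL effect sizes
#'
#' For every gene with both cis- and trans-eQTL, compares the mean absolute
#' effect of its cis-eQTL to that of its trans-eQTL with the Wilcoxon
#' signed-rank test on the paired per-gene values.
#'
#' @param eqtl Tidy eQTL tibble with columns `gene`, `beta`, `type`.
#' @return Tibble with `n_genes`, `median_cis`, `median_trans`, `statistic`,
#'   `p_value`.
#' @export
cis_trans_effect_test <- function(eqtl) {
  per_gene <- dplyr::summarise(
    dplyr::group_by(eqtl, .data$gene, .data$type),
    effect = mean(abs(.data$beta)), .groups = "drop")
  wide <- tidyr::pivot_wider(per_gene, names_from = "type",
                             values_from = "effect")
  if (!all(c("cis", "trans") %in% names(wide))) {
    stop("need genes with both cis- and trans-eQTL")
  }
  wide <- wide[!is.na(wide$cis) & !is.na(wide$trans), ]
  if (nrow(wide) < 1) stop("no gene has both cis- and trans-eQTL")
  wt <- stats::wilcox.test(wide$cis, wide$trans, paired = TRUE, exact = FALSE)
  tibble::tibble(n_genes = nrow(wide),
                 median_cis = stats::median(wide$cis),
                 median_trans = stats::median(wide$trans),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value)
}

#' Odds ratio for a 2x2 contingency of window properties
#'
#' Convenience helper for questions like "are eQTL hotspot windows enriched
#' for QTL?". Takes two logical vectors over the same windows, builds the
#' 2x2 table, and reports the odds ratio (with a Haldane-Anscombe 0.5
#' correction when a cell is empty) and the chi-square test p-value.
#'
#' @param a,b Logical vectors of equal length.
#' @return Tibble with `odds_ratio`, `statistic`, `p_value` and the four
#'   cell counts.
#' @export
odds_ratio_test <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), length(a) == length(b))
  n11 <- sum(a & b); n10 <- sum(a & !b)
  n01 <- sum(!a & b); n00 <- sum(!a & !b)
  cells <- c(n11, n10, n01, n00)
  adj <- if (any(cells == 0)) 0.5 else 0
  or <- ((n11 + adj) * (n00 + adj)) / ((n10 + adj) * (n01 + adj))
  ct <- suppressWarnings(stats::chisq.test(matrix(cells, 2)))
  tibble::tibble(odds_ratio = or, statistic = unname(ct$statistic),
                 p_value = ct$p.value, n11 = n11, n10 = n10, n01 = n01,
                 n00 = n00)
}
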