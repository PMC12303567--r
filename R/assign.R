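#' Expected distance between two probabilistic genotypes
#'
#' For genotype vectors with entries in \[0, 1\] (probabilities of the RM
#' allele), the expected number of mismatching sites under independent
#' Bernoulli draws is `sum(g_c + g_s - 2 * g_c * g_s)`. On hard {0, 1}
#' vectors this reduces to the Hamming distance; a site where either vector
#' equals 1/2 contributes exactly 1/2 whatever the other carries.
#'
#' @param g_c,g_s Numeric vectors of equal length with entries in \[0, 1\].
#' @return Non-negative scalar.
#' @export
expected_distance <- function(g_c, g_s) {
  if (length(g_c) != length(g_s)) stop("genotype vectors differ in length")
  if (any(g_c < 0 | g_c > 1 | g_s < 0 | g_s > 1, na.rm = TRUE)) {
    stop("genotype entries must lie in [0, 1]")
  }
  sum(g_c + g_s - 2 * g_c * g_s)
}

# All pairwise expected distances: cells (rows of G) x strains (rows of P).
expected_distance_matrix <- function(G, P) {
  stopifnot(ncol(G) == ncol(P))
  outer(rowSums(G), rowSums(P), "+") - 2 * tcrossprod(G, P)
}

#' Relatedness of two genotype vectors (adjusted R-squared)
#'
#' Both vectors are rounded to hard calls (ties at 0.5 go to RM) and the
#' simple-regression R-squared of one on the other is adjusted for degrees
#' of freedom, `1 - (1 - R2) * (n - 1) / (n - 2)`. R-squared is sign-blind,
#' so the sign of the regression slope is returned alongside as the
#' `"slope_sign"` attribute (-1 flags perfect anti-correlation).
#'
#' @param g_c,g_s Genotype vectors (>= 3 sites).
#' @return Adjusted R-squared, with attribute `slope_sign`.
#' @export
relatedness <- function(g_c, g_s) {
  if (length(g_c) != length(g_s)) stop("genotype vectors differ in length")
  n <- length(g_c)
  if (n < 3) stop("relatedness needs at least 3 sites")
  a <- as.numeric(g_c >= 0.5)
  b <- as.numeric(g_s >= 0.5)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance in a rounded genotype vector; relatedness set to 0")
    return(structure(0, slope_sign = 0))
  }
  r <- stats::cor(a, b)
  r2 <- r^2
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(adj, slope_sign = sign(r))
}

# Site-wise shuffle of panel columns across strains: preserves per-site
# allele frequencies, destroys strain identity and linkage.
shuffle_panel <- function(panel) {
  apply(panel, 2, sample)
}

#' Assign cells to reference strains with a permutation null
#'
#' Each cell's posterior genotype is matched to the reference panel strain
#' minimizing the expected distance. Significance is assessed against
#' `n_null` randomly generated batches of the panel's size: the permutation
#' p-value is `(1 + # null best distances <= observed) / (1 + n_null)`,
#' adjusted across cells by Benjamini-Hochberg, and a cell is assigned when
#' its q-value falls below `fdr`. Null batches are freshly simulated F2
#' genomes on the same genetic map (`null = "cross"`, the default), which
#' preserves both allele frequencies and linkage: HMM-imputed posteriors
#' are block-structured, and a null without linkage (`null = "shuffle"`,
#' site-wise shuffling of panel columns) understates the spread of
#' best-match distances and is anti-conservative. When `counts` are
#' supplied, doublets are flagged with [flag_doublets()] and excluded from
#' assignment.
#'
#' @param posteriors A `cell_posteriors` object (or a cells x sites matrix,
#'   in which case `map` must be given for the simulated null).
#' @param panel Reference genotype matrix (strains x sites).
#' @param n_null Number of null batches (>= 19).
#' @param fdr FDR threshold for assignment.
#' @param counts Optional allele-count tibble used for doublet flagging.
#' @param doublet_r2_max Top-two-strain genotype R-squared ceiling for the
#'   doublet rule.
#' @param seed Integer seed for the null batches.
#' @param null `"cross"` (simulated recombinant genomes) or `"shuffle"`
#'   (site-wise column shuffling).
#' @param map The `genetic_map`; only needed for `null = "cross"` when
#'   `posteriors` is a plain matrix.
#' @return A tibble with one row per cell: `barcode`, `strain`, `distance`,
#'   `strain2`, `distance2`, `relatedness`, `slope_sign`, `p`, `q`,
#'   `doublet`, `assigned`.
#' @export
assign_cells <- function(posteriors, panel, n_null = 100, fdr = 0.05,
                         counts = NULL, doublet_r2_max = 0.1, seed = 1,
                         null = c("cross", "shuffle"), map = NULL) {
  G <- if (inherits(posteriors, "cell_posteriors")) posteriors$prob else posteriors
  null <- match.arg(null)
  if (is.null(map) && inherits(posteriors, "cell_posteriors")) {
    map <- posteriors$map
  }
  stopifnot(is.matrix(G), is.matrix(panel))
  if (nrow(panel) < 2) stop("the reference panel needs at least 2 strains")
  if (n_null < 19) stop("n_null must be at least 19")
  if (null == "cross" && is.null(map)) {
    stop("null = \"cross\" needs the genetic map (pass `map`)")
  }
  D <- expected_distance_matrix(G, panel)
  best_i <- apply(D, 1, which.min)
  best_d <- D[cbind(seq_len(nrow(D)), best_i)]
  D2 <- D
  D2[cbind(seq_len(nrow(D)), best_i)] <- Inf
  second_i <- apply(D2, 1, which.min)
  second_d <- D2[cbind(seq_len(nrow(D2)), second_i)]

  null_best <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      Pb <- if (null == "cross") {
        simulate_cross(map, nrow(panel),
                       seed = sample.int(.Machine$integer.max, 1))
      } else {
        shuffle_panel(panel)
      }
      row_mins(expected_distance_matrix(G, Pb))
    }, numeric(nrow(G)))
  })
  if (is.null(dim(null_best))) null_best <- matrix(null_best, nrow = nrow(G))
  p <- (1 + rowSums(null_best <= best_d)) / (1 + n_null)
  q <- stats::p.adjust(p, method = "BH")

  rel <- numeric(nrow(G)); slope <- numeric(nrow(G))
  for (i in seq_len(nrow(G))) {
    v <- suppressWarnings(relatedness(G[i, ], panel[best_i[i], ]))
    rel[i] <- as.numeric(v); slope[i] <- attr(v, "slope_sign")
  }

  res <- tibble::tibble(
    barcode = rownames(G) %||% as.character(seq_len(nrow(G))),
    strain = rownames(panel)[best_i],
    distance = best_d,
    strain2 = rownames(panel)[second_i],
    distance2 = second_d,
    relatedness = rel,
    slope_sign = slope,
    p = p,
    q = q,
    doublet = FALSE,
    assigned = q < fdr
  )
  if (!is.null(counts)) {
    params <- if (inherits(posteriors, "cell_posteriors")) posteriors$params
    res$doublet <- flag_doublets(res, counts, panel, params = params,
                                 r2_max = doublet_r2_max)
    res$assigned <- res$assigned & !res$doublet
  }
  res
}

#' Flag doublet barcodes
#'
#' A barcode is called a doublet when three clauses hold, evaluated in this
#' order: (1) its covered-site count is at or above the third quartile of
#' the covered-site distribution (a doublet carries two cells' reads);
#' (2) it has no significant assignment, in the sense that its reads misfit
#' its best-matching strain: the number of reads disagreeing with the best
#' strain's alleles exceeds what the error/swap channel allows, by a
#' one-sided binomial test at level `alpha` against the expected mismatch
#' rate `(1 - s) * eps + s / 2`; and (3) its two best-matching strains are
#' themselves unrelated (rounded-genotype R-squared below `r2_max`), so the
#' misfit is not explained by two near-identical references splitting one
#' lineage's reads. Clause 2 is what separates a mixture of two genomes
#' (about a quarter of its reads contradict either parent) from a clean
#' cell, and its level is the singlet false-flag rate.
#'
#' @param assignments Tibble from [assign_cells()].
#' @param counts Allele-count tibble (`barcode`, `site`, `rm`, `by`).
#' @param panel Reference genotype matrix.
#' @param params Optional [hmm_params()]; when given, the expected mismatch
#'   rate is derived from its error and swap rates.
#' @param mismatch_rate Expected per-read mismatch rate for a true match;
#'   overrides `params`. When both are NULL it is estimated as the median
#'   per-cell mismatch fraction (most barcodes are clean singlets).
#' @param alpha Level of the per-cell misfit test (clause 2).
#' @param r2_max Mutual-relatedness ceiling in clause 3.
#' @return Logical vector along the rows of `assignments`.
#' @export
flag_doublets <- function(assignments, counts, panel, params = NULL,
                          mismatch_rate = NULL, alpha = 0.05, r2_max = 0.1) {
  cov_tab <- table(counts$barcode)
  coverage <- as.numeric(cov_tab[assignments$barcode])
  coverage[is.na(coverage)] <- 0
  q3 <- stats::quantile(coverage, 0.75, names = FALSE)

  # reads disagreeing with the best strain, per cell
  best_allele <- panel[cbind(match(assignments$strain[match(counts$barcode,
                                                            assignments$barcode)],
                                   rownames(panel)),
                             counts$site)]
  mis_reads <- ifelse(best_allele >= 0.5, counts$by, counts$rm)
  mis_reads[is.na(mis_reads)] <- 0
  tot_reads <- counts$rm + counts$by
  mis_by_cell <- tapply(mis_reads, counts$barcode, sum)
  tot_by_cell <- tapply(tot_reads, counts$barcode, sum)
  mis <- as.numeric(mis_by_cell[assignments$barcode])
  tot <- as.numeric(tot_by_cell[assignments$barcode])
  mis[is.na(mis)] <- 0; tot[is.na(tot)] <- 0

  if (is.null(mismatch_rate)) {
    mismatch_rate <- if (!is.null(params)) {
      (1 - params$swap_rate) * params$error_rate + params$swap_rate / 2
    } else {
      stats::median(mis[tot > 0] / tot[tot > 0])
    }
  }
  mismatch_rate <- min(max(mismatch_rate, 1e-6), 1 - 1e-6)

  flags <- logical(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    if (coverage[i] < q3) next
    if (tot[i] == 0) next
    p_fit <- stats::pbinom(mis[i] - 1, tot[i], mismatch_rate,
                           lower.tail = FALSE)
    if (p_fit >= alpha) next          # reads fit the best strain: assigned
    s1 <- panel[assignments$strain[i], ]
    s2 <- panel[assignments$strain2[i], ]
    mutual <- suppressWarnings(as.numeric(relatedness(s1, s2)))
    if (mutual < r2_max) flags[i] <- TRUE
  }
  flags
}

#' Per-strain consensus genotype and expression profiles
#'
#' Cells assigned to the same strain form a lineage. The consensus genotype
#' is the per-site median of the lineage's posterior genotypes (robust to
#' outlier cells); the consensus expression profile is the UMI column of the
#' lineage cell with the largest total UMI count (the best-covered
#' transcriptome). Strains with no assigned cells are dropped.
#'
#' @param assignments Tibble from [assign_cells()]; only rows with
#'   `assigned == TRUE` contribute.
#' @param posteriors A `cell_posteriors` object or cells x sites matrix.
#' @param umi Optional genes x cells matrix (sparse or dense).
#' @return List with `genotype` (strains x sites matrix), `expression`
#'   (genes x strains matrix or NULL) and `strains` (tibble: strain,
#'   n_cells, consensus_cell).
#' @export
consensus_profiles <- function(assignments, posteriors, umi = NULL) {
  G <- if (inherits(posteriors, "cell_posteriors")) posteriors$prob else posteriors
  keep <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(keep) == 0) stop("no assigned cells; cannot build consensus profiles")
  strains <- sort(unique(keep$strain))
  geno <- matrix(NA_real_, nrow = length(strains), ncol = ncol(G),
                 dimnames = list(strains, colnames(G)))
  consensus_cell <- character(length(strains))
  n_cells <- integer(length(strains))
  totals <- if (!is.null(umi)) Matrix::colSums(umi) else NULL
  for (k in seq_along(strains)) {
    cells <- keep$barcode[keep$strain == strains[k]]
    n_cells[k] <- length(cells)
    block <- G[cells, , drop = FALSE]
    geno[k, ] <- apply(block, 2, stats::median)
    if (!is.null(umi)) {
      consensus_cell[k] <- cells[which.max(totals[cells])]
    }
  }
  expr <- NULL
  if (!is.null(umi)) {
    expr <- as.matrix(umi[, consensus_cell, drop = FALSE])
    colnames(expr) <- strains
  }
  list(genotype = geno, expression = expr,
       strains = tibble::tibble(strain = strains, n_cells = n_cells,
                                consensus_cell = if (is.null(umi)) NA_character_
                                                 else consensus_cell))
}

#' Normalize a consensus expression matrix for model fitting
#'
#' Standardizes each gene to mean 0, variance 1 across strains, then divides
#' each strain's profile by that strain's total raw count, in that order, to
#' control for molecule-count bias across cells. Zero-variance genes are
#' dropped with a message.
#'
#' @param expression Genes x strains matrix of raw consensus UMI counts.
#' @return Strains x genes matrix, normalized, ready to use as a random
#'   design or eQTL response.
#' @export
normalize_expression <- function(expression) {
  stopifnot(is.matrix(expression))
  totals <- colSums(expression)
  if (any(totals == 0)) stop("strains with zero total counts cannot be normalized")
  sds <- apply(expression, 1, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    message("dropping ", sum(drop), " zero-variance gene(s) before normalization")
    expression <- expression[!drop, , drop = FALSE]
  }
  z <- t(scale(t(expression)))
  out <- t(sweep(z, 2, totals, "/"))
  out
}

# rowMins without a matrixStats dependency
row_mins <- function(m) {
  do.call(pmin, as.data.frame(m))
}

#' Pluggable expression pre-transform
#'
#' Hook for denoising the consensus expression matrix before variance
#' partitioning or eQTL mapping. Ships with the identity and a simple
#' low-rank smoother (truncated SVD reconstruction); external denoisers
#' can be slotted in by passing any function through the calling code in
#' their place.
#'
#' @param expression Strains x genes numeric matrix.
#' @param method `"identity"` or `"low_rank"`.
#' @param rank Rank of the truncated reconstruction.
#' @return A matrix of the same shape.
#' @export
smooth_expression <- function(expression, method = c("identity", "low_rank"),
                              rank = 10) {
  method <- match.arg(method)
  stopifnot(is.matrix(expression))
  if (method == "identity") return(expression)
  rank <- min(rank, nrow(expression) - 1, ncol(expression))
  ctr <- colMeans(expression)
  sv <- svd(sweep(expression, 2, ctr), nu = rank, nv = rank)
  out <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
  out <- sweep(out, 2, ctr, "+")
  dimnames(out) <- dimnames(expression)
  out
}
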