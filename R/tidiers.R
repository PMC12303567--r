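#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a forward-search QTL model
#'
#' @param x A `qtl_fit`.
#' @param map Optional `genetic_map` to attach genomic coordinates.
#' @param ... Unused.
#' @return Tibble with one row per selected locus: `site`, `locus`,
#'   `order`, `beta` (and `chrom`, `pos`, `cm` when a map is given).
#' @export
tidy.qtl_fit <- function(x, map = NULL, ...) {
  out <- x$sites
  if (!is.null(map)) {
    if (!inherits(map, "genetic_map")) map <- genetic_map(map)
    out <- dplyr::left_join(out, map[c("site", "chrom", "pos", "cm")],
                            by = "site")
  }
  out
}

#' @rdname tidy.qtl_fit
#' @export
glance.qtl_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_loci = nrow(x$sites), rss = x$rss,
                 lambda = x$lambda, objective = x$objective, r2 = x$r2)
}

#' Tidy a REML variance-component fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return Tibble with one row per variance component: `component`,
#'   `sigma2`, `se`, `fraction` (of total variance).
#' @export
tidy.reml_fit <- function(x, ...) {
  tot <- sum(x$sigma2)
  tibble::tibble(component = names(x$sigma2), sigma2 = unname(x$sigma2),
                 se = unname(x$se),
                 fraction = unname(x$sigma2) / tot)
}

#' @rdname tidy.reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(n = x$n, varexp = x$varexp, loglik = x$loglik,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a variance partition
#'
#' A `variance_partition` already is a tibble of components; `tidy()`
#' strips the extra class, `glance()` summarises it to one row.
#'
#' @param x A `variance_partition`.
#' @param ... Unused.
#' @export
tidy.variance_partition <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.variance_partition
#' @export
glance.variance_partition <- function(x, ...) {
  out <- tidyr::pivot_wider(tibble::as_tibble(unclass(x))[c("component",
                                                            "fraction")],
                            names_from = "component",
                            values_from = "fraction")
  out$n <- attr(x, "n")
  out
}

#' Tidy cell posterior genotypes into sparse triplets
#'
#' @param x A `cell_posteriors`.
#' @param threshold Posteriors within `threshold` of the flat prior 0.5 are
#'   omitted (0 keeps everything).
#' @param ... Unused.
#' @return Tibble with `barcode`, `site`, `p_rm`.
#' @export
tidy.cell_posteriors <- function(x, threshold = 0, ...) {
  keep <- abs(x$prob - 0.5) >= threshold
  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(barcode = x$barcodes[idx[, 1]],
                 site = as.integer(colnames(x$prob)[idx[, 2]]),
                 p_rm = x$prob[idx])
}

#' @rdname tidy.cell_posteriors
#' @export
glance.cell_posteriors <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$prob), n_sites = ncol(x$prob),
                 mean_loglik = mean(x$loglik))
}

#' Tidy an HMM parameter fit
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(error_rate = x$params$error_rate,
                 swap_rate = x$params$swap_rate,
                 rec_scale = x$params$rec_scale,
                 loglik = x$trajectory[length(x$trajectory)],
                 iterations = x$iterations, converged = x$converged)
}

#' @rdname tidy.eqtl_set
#' @export
glance.eqtl_set <- function(x, ...) {
  tibble::tibble(n_genes = length(x$models), lambda = x$lambda, n = x$n,
                 median_eqtl = stats::median(x$summary$n_eqtl),
                 total_eqtl = sum(x$summary$n_eqtl))
}

#' Plot a QTL model along the genome
#'
#' Effect sizes of the selected loci at their genomic positions, faceted by
#' chromosome.
#'
#' @param object A `qtl_fit`.
#' @param map A `genetic_map` (required for coordinates).
#' @param ... Unused.
#' @export
autoplot.qtl_fit <- function(object, map, ...) {
  d <- tidy(object, map = map)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1000, y = .data$beta)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos / 1000, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "position (kb)", y = "effect size (standardized)") +
    ggplot2::theme_minimal()
}

#' Plot a variance partition as stacked fractions
#'
#' @param object A `variance_partition`.
#' @param ... Unused.
#' @export
autoplot.variance_partition <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = rev(d$component))
  ggplot2::ggplot(d, ggplot2::aes(x = "trait", y = .data$fraction,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of variance") +
    ggplot2::theme_minimal()
}

#' Plot posterior genotypes of a few cells along one chromosome
#'
#' @param object A `cell_posteriors`.
#' @param cells Barcodes to display (default: first 4).
#' @param chrom Chromosome to display (default: the first in the map).
#' @param ... Unused.
#' @export
autoplot.cell_posteriors <- function(object, cells = NULL, chrom = NULL, ...) {
  if (is.null(cells)) cells <- utils::head(object$barcodes, 4)
  map <- object$map
  if (is.null(chrom)) chrom <- map$chrom[1]
  idx <- which(map$chrom == chrom)
  d <- dplyr::bind_rows(lapply(cells, function(b) {
    tibble::tibble(barcode = b, pos = map$pos[idx],
                   p_rm = object$prob[b, idx])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1000, y = .data$p_rm)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$barcode)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = paste0(chrom, " position (kb)"), y = "P(RM)") +
    ggplot2::theme_minimal()
}

#' Plot eQTL counts per genomic window with hotspot flags
#'
#' @param object A `hotspot_table`.
#' @param ... Unused.
#' @export
autoplot.hotspot_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e3,
                                  y = .data$n_genes, fill = .data$hotspot)) +
    ggplot2::geom_col(width = 24) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "window midpoint (kb)", y = "regulated genes") +
    ggplot2::theme_minimal()
}
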