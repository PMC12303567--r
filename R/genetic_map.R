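#' Build a validated genetic map
#'
#' A genetic map is a tibble with one row per biallelic polymorphic site,
#' sorted by chromosome and physical position, carrying both physical
#' (base-pair) and genetic (centimorgan) coordinates. Physical positions are
#' 1-based inclusive. All downstream stages (meiosis simulation, HMM
#' transition probabilities, hotspot windows, cis/trans classification) key
#' sites by their row index in this table, exposed as the `site` column.
#'
#' @param map A data frame with columns `chrom` (character), `pos`
#'   (integer base pairs) and `cm` (non-negative numeric, centimorgans).
#' @return A tibble of class `genetic_map` with an integer `site` index
#'   column prepended.
#' @examples
#' genetic_map(data.frame(chrom = "chrI", pos = c(100L, 900L), cm = c(0, 0.4)))
#' @export
genetic_map <- function(map) {
  stopifnot(is.data.frame(map))
  req <- c("chrom", "pos", "cm")
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols) > 0) {
    stop("genetic map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  map <- tibble::as_tibble(map[req])
  if (nrow(map) == 0) stop("genetic map must contain at least one site")
  if (anyNA(map)) stop("genetic map contains missing values")
  if (any(map$cm < 0)) stop("genetic positions (cm) must be non-negative")
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    stop("genetic map must be sorted by (chrom, pos)")
  }
  by_chrom <- split(seq_len(nrow(map)), map$chrom)
  for (idx in by_chrom) {
    if (anyDuplicated(map$pos[idx])) {
      stop("duplicated physical positions within a chromosome")
    }
    if (is.unsorted(map$cm[idx])) {
      stop("genetic positions must be non-decreasing within a chromosome")
    }
  }
  map <- dplyr::mutate(map, site = dplyr::row_number(), .before = 1)
  class(map) <- c("genetic_map", class(map))
  map
}

#' Simulate a yeast-like genetic map
#'
#' Places `n_sites` polymorphic sites uniformly at random over a genome of
#' `n_chrom` chromosomes totalling `genome_bp` base pairs, with genetic
#' distance accumulating at `cm_per_kb` centimorgans per kilobase (no
#' recombination-rate heterogeneity). The defaults resemble the S. cerevisiae
#' genome: 16 chromosomes, 12 Mb, roughly 0.38 cM/kb, so the full map is about
#' 4,500 cM. For HMM-oriented simulations where the real study's marker
#' density (about 0.1 cM between adjacent markers) matters more than total
#' map length, pass a larger `cm_per_kb`-adjusted `genome_bp` or use
#' `spacing_cm` to fix the mean inter-site genetic distance directly.
#'
#' @param n_sites Number of polymorphic sites.
#' @param n_chrom Number of chromosomes.
#' @param genome_bp Total genome length in base pairs.
#' @param cm_per_kb Genetic map expansion in cM per kb.
#' @param spacing_cm If non-NULL, overrides `cm_per_kb` so that the mean
#'   genetic distance between adjacent sites equals this value.
#' @param seed Integer seed; site placement is deterministic given the seed.
#' @return A `genetic_map` tibble.
#' @export
sim_genetic_map <- function(n_sites = 2000, n_chrom = 16, genome_bp = 12e6,
                            cm_per_kb = 0.38, spacing_cm = NULL, seed = 1) {
  stopifnot(n_sites >= 1, n_chrom >= 1, genome_bp >= n_sites)
  if (!is.null(spacing_cm)) {
    # total map length = spacing * n_sites; convert to per-kb rate
    cm_per_kb <- spacing_cm * n_sites / (genome_bp / 1000)
  }
  withr::with_seed(seed, {
    # chromosome sizes roughly even with 20% jitter, summing to genome_bp
    raw <- stats::runif(n_chrom, 0.8, 1.2)
    sizes <- pmax(round(genome_bp * raw / sum(raw)), n_sites)
    chrom_names <- sprintf("chr%02d", seq_len(n_chrom))
    n_per <- as.vector(stats::rmultinom(1, n_sites, sizes / sum(sizes)))
    # every chromosome keeps at least one site when possible
    while (any(n_per == 0) && sum(n_per > 1) > 0) {
      i <- which(n_per == 0)[1]
      j <- which.max(n_per)
      n_per[i] <- n_per[i] + 1L
      n_per[j] <- n_per[j] - 1L
    }
    pieces <- lapply(seq_len(n_chrom), function(i) {
      if (n_per[i] == 0) return(NULL)
      pos <- sort(sample.int(sizes[i], n_per[i]))
      tibble::tibble(chrom = chrom_names[i], pos = pos,
                     cm = pos / 1000 * cm_per_kb)
    })
    genetic_map(dplyr::bind_rows(pieces))
  })
}

#' Recombination fractions between adjacent sites
#'
#' Haldane map function (no crossover interference):
#' r = (1 - exp(-2 d)) / 2 with d the inter-site distance in Morgans.
#' The first site of each chromosome gets NA (no preceding interval).
#'
#' @param map A `genetic_map`.
#' @param scale Multiplier applied to map distances before conversion
#'   (the HMM's global recombination scale).
#' @return Numeric vector aligned with `map$site`.
#' @export
recomb_fraction <- function(map, scale = 1) {
  stopifnot(inherits(map, "genetic_map"), scale >= 0)
  d <- c(NA_real_, diff(map$cm)) / 100 * scale
  d[c(TRUE, map$chrom[-1] != map$chrom[-nrow(map)])] <- NA_real_
  0.5 * (1 - exp(-2 * d))
}
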