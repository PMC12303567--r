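#' Simulate an F2 segregant panel from a haploid-by-haploid cross
#'
#' Generates haploid two-state genotypes for `n_segregants` recombinant
#' offspring of a BY x RM style cross. Each chromosome is an independent
#' mosaic of parental blocks: the leftmost site's allele is Bernoulli(1/2)
#' and the allele switches between adjacent sites with the Haldane
#' recombination fraction r = (1 - exp(-2d))/2, d the inter-site genetic
#' distance in Morgans. Crossovers are therefore Poisson along the genetic
#' map with no interference, and the marginal RM-allele frequency at every
#' site is 1/2.
#'
#' @param map A `genetic_map`.
#' @param n_segregants Number of segregants to simulate.
#' @param seed Integer seed; the panel is reproducible bit-for-bit.
#' @return An integer matrix (segregants x sites) with entries in {0, 1}
#'   (1 = RM allele), rownames `seg0001`... and colnames the site indices.
#' @export
simulate_cross <- function(map, n_segregants, seed = 1) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  stopifnot(n_segregants >= 1)
  S <- nrow(map)
  r <- recomb_fraction(map)
  withr::with_seed(seed, {
    G <- matrix(0L, nrow = n_segregants, ncol = S)
    # switch indicator per interval; chromosome starts draw a fresh allele
    for (i in seq_len(S)) {
      if (is.na(r[i])) {
        G[, i] <- as.integer(stats::runif(n_segregants) < 0.5)
      } else {
        flip <- stats::runif(n_segregants) < r[i]
        G[, i] <- ifelse(flip, 1L - G[, i - 1L], G[, i - 1L])
      }
    }
    dimnames(G) <- list(sprintf("seg%04d", seq_len(n_segregants)), map$site)
    G
  })
}

#' Describe a genetic architecture to plant in a simulated cross
#'
#' Collects the counts and effect-size distributions for fitness QTL,
#' cis-eQTL, trans-eQTL, eQTL hotspots and residual noise used by
#' [plant_architecture()]. Effect sizes are drawn uniformly from
#' `[min, max]` with random sign; all effects and noise SDs share the unit
#' of the trait (fitness in arbitrary units, expression in log2 units).
#'
#' @param n_qtl Number of fitness QTL.
#' @param qtl_effect Length-2 numeric, |effect| range for fitness QTL.
#' @param fitness_noise_sd Residual SD of fitness.
#' @param n_genes Number of genes.
#' @param cis_prob Probability that a gene carries a cis-eQTL.
#' @param cis_effect |effect| range for cis-eQTL (log2 expression units).
#' @param n_hotspots Number of planted trans-regulatory hotspots; each is a
#'   single site regulating `hotspot_targets` genes.
#' @param hotspot_targets Genes regulated per hotspot.
#' @param hotspot_effect |effect| range for hotspot trans-eQTL.
#' @param bg_trans_prob Probability that a gene carries one additional
#'   diffuse background trans-eQTL at a random site.
#' @param bg_trans_effect |effect| range for background trans-eQTL.
#' @param expr_noise_sd Residual SD of log2 expression.
#' @param baseline_log2 Length-2 range of per-gene baseline mean log2
#'   expression (sets relative UMI abundance downstream).
#' @param gene_length_bp Gene body length used when placing genes.
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(n_qtl = 20,
                              qtl_effect = c(0.3, 0.6),
                              fitness_noise_sd = 1,
                              n_genes = 200,
                              cis_prob = 0.3,
                              cis_effect = c(0.5, 1.5),
                              n_hotspots = 3,
                              hotspot_targets = 20,
                              hotspot_effect = c(0.5, 1.5),
                              bg_trans_prob = 0.3,
                              bg_trans_effect = c(0.3, 1),
                              expr_noise_sd = 1,
                              baseline_log2 = c(1, 6),
                              gene_length_bp = 1500) {
  spec <- list(n_qtl = n_qtl, qtl_effect = qtl_effect,
               fitness_noise_sd = fitness_noise_sd, n_genes = n_genes,
               cis_prob = cis_prob, cis_effect = cis_effect,
               n_hotspots = n_hotspots, hotspot_targets = hotspot_targets,
               hotspot_effect = hotspot_effect, bg_trans_prob = bg_trans_prob,
               bg_trans_effect = bg_trans_effect, expr_noise_sd = expr_noise_sd,
               baseline_log2 = baseline_log2, gene_length_bp = gene_length_bp)
  stopifnot(n_qtl >= 0, n_genes >= 1, cis_prob >= 0, cis_prob <= 1,
            fitness_noise_sd >= 0, expr_noise_sd >= 0,
            length(qtl_effect) == 2, length(cis_effect) == 2)
  class(spec) <- "architecture_spec"
  spec
}

draw_effects <- function(n, range) {
  if (n == 0) return(numeric(0))
  stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Plant a genetic architecture on a simulated panel
#'
#' Chooses fitness QTL, cis-/trans-eQTL and hotspot sites, then builds the
#' strain-level ground truth: fitness = sum of QTL effects times genotype
#' plus Gaussian noise, and per-gene mean log2 expression = baseline + sum
#' of eQTL effects times genotype plus Gaussian noise. Cis-eQTL are placed
#' by construction inside the target gene's cis window (1,000 bp upstream of
#' the TSS to 200 bp downstream of the gene end, strand-aware); hotspot
#' sites regulate many genes in trans from a single 25-kb window.
#'
#' @param panel Segregant genotype matrix from [simulate_cross()].
#' @param map The `genetic_map` the panel was simulated on.
#' @param spec An [architecture_spec()].
#' @param seed Integer seed.
#' @return A list with elements
#'   `architecture` (list of tibbles `qtl`, `eqtl`, `hotspots`, `genes`,
#'   plus the realised `fitness_h2`),
#'   `fitness` (named vector over strains), and
#'   `expression` (strains x genes matrix of mean log2 expression).
#' @export
plant_architecture <- function(panel, map, spec = architecture_spec(), seed = 1) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  stopifnot(is.matrix(panel), ncol(panel) == nrow(map))
  S <- nrow(map)
  if (spec$n_qtl > S) stop("requested more fitness QTL than available sites")
  withr::with_seed(seed, {
    n <- nrow(panel)
    ## fitness layer -----------------------------------------------------
    qtl_sites <- sort(sample.int(S, spec$n_qtl))
    qtl_beta <- draw_effects(spec$n_qtl, spec$qtl_effect)
    genetic <- if (spec$n_qtl > 0) {
      drop(panel[, qtl_sites, drop = FALSE] %*% qtl_beta)
    } else rep(0, n)
    fitness <- genetic + stats::rnorm(n, 0, spec$fitness_noise_sd)
    names(fitness) <- rownames(panel)
    h2 <- if (stats::var(fitness) > 0) stats::var(genetic) / stats::var(fitness) else 0

    ## gene placement ----------------------------------------------------
    chrom_len <- tapply(map$pos, map$chrom, max)
    n_hot <- min(spec$n_hotspots, S)
    hot_sites <- if (n_hot > 0) sort(sample.int(S, n_hot)) else integer(0)
    # hotspot windows are the 25-kb tiles containing the hotspot sites
    hotspots <- tibble::tibble(
      chrom = map$chrom[hot_sites],
      start = ((map$pos[hot_sites] - 1L) %/% 25000L) * 25000L + 1L,
      end = ((map$pos[hot_sites] - 1L) %/% 25000L + 1L) * 25000L,
      site = hot_sites
    )

    cis_flag <- stats::runif(spec$n_genes) < spec$cis_prob
    cis_site <- rep(NA_integer_, spec$n_genes)
    cis_site[cis_flag] <- sample.int(S, sum(cis_flag), replace = TRUE)
    strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
    gene_chrom <- character(spec$n_genes)
    gene_start <- integer(spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      if (cis_flag[g]) {
        # place gene so its cis site sits a little upstream of the TSS
        s <- cis_site[g]
        gene_chrom[g] <- map$chrom[s]
        off <- sample(50:900, 1)
        gene_start[g] <- if (strand[g] == "+") map$pos[s] + off
          else max(1L, map$pos[s] - off - spec$gene_length_bp)
      } else {
        gene_chrom[g] <- sample(names(chrom_len), 1)
        gene_start[g] <- sample.int(max(1L, chrom_len[[gene_chrom[g]]]), 1)
      }
    }
    genes <- tibble::tibble(
      gene = sprintf("gene%04d", seq_len(spec$n_genes)),
      chrom = gene_chrom,
      start = pmax(1L, as.integer(gene_start)),
      end = pmax(1L, as.integer(gene_start)) + spec$gene_length_bp - 1L,
      strand = strand,
      baseline = stats::runif(spec$n_genes, spec$baseline_log2[1],
                              spec$baseline_log2[2])
    )

    ## eQTL layer --------------------------------------------------------
    eqtl <- list()
    if (any(cis_flag)) {
      eqtl$cis <- tibble::tibble(
        gene = genes$gene[cis_flag],
        site = cis_site[cis_flag],
        beta = draw_effects(sum(cis_flag), spec$cis_effect),
        kind = "cis"
      )
    }
    if (n_hot > 0 && spec$hotspot_targets > 0) {
      eqtl$hot <- dplyr::bind_rows(lapply(seq_len(n_hot), function(h) {
        targets <- sample(genes$gene, min(spec$hotspot_targets, spec$n_genes))
        tibble::tibble(gene = targets, site = hot_sites[h],
                       beta = draw_effects(length(targets), spec$hotspot_effect),
                       kind = "hotspot")
      }))
    }
    bg_flag <- stats::runif(spec$n_genes) < spec$bg_trans_prob
    if (any(bg_flag)) {
      eqtl$bg <- tibble::tibble(
        gene = genes$gene[bg_flag],
        site = sample.int(S, sum(bg_flag), replace = TRUE),
        beta = draw_effects(sum(bg_flag), spec$bg_trans_effect),
        kind = "trans"
      )
    }
    eqtl <- dplyr::bind_rows(eqtl)
    if (nrow(eqtl) == 0) {
      eqtl <- tibble::tibble(gene = character(), site = integer(),
                             beta = numeric(), kind = character())
    }

    ## strain-level mean expression --------------------------------------
    expr <- matrix(rep(genes$baseline, each = n), nrow = n,
                   dimnames = list(rownames(panel), genes$gene))
    if (nrow(eqtl) > 0) {
      for (g in unique(eqtl$gene)) {
        rows <- eqtl[eqtl$gene == g, ]
        expr[, g] <- expr[, g] +
          drop(panel[, rows$site, drop = FALSE] %*% rows$beta)
      }
    }
    expr <- expr + matrix(stats::rnorm(n * spec$n_genes, 0, spec$expr_noise_sd),
                          nrow = n)

    list(
      architecture = list(
        qtl = tibble::tibble(site = qtl_sites, beta = qtl_beta),
        eqtl = eqtl,
        hotspots = hotspots,
        genes = genes,
        fitness_h2 = h2
      ),
      fitness = fitness,
      expression = expr
    )
  })
}

#' Observation-layer parameters for the single-cell simulator
#'
#' Defaults follow the study conditions of a pooled yeast single-cell
#' RNA-seq run: about 3% of polymorphic sites covered by at least one read
#' per cell, a per-read sequencing/RT error rate, a per-read index-swap rate
#' (a swapped read draws its allele from the pool frequency at the site),
#' about 4.83 barcodes per segregant and a 10% doublet rate. Per-cell
#' library sizes are log-normal and UMI counts per gene negative binomial;
#' dropout arises purely from sampling.
#'
#' @param breadth Expected fraction of sites with >= 1 read per cell.
#' @param error_rate Per-read sequencing/RT error probability.
#' @param swap_rate Per-read index-swap probability.
#' @param cells_per_strain Mean barcodes per segregant.
#' @param doublet_rate Fraction of barcodes that are doublets.
#' @param extra_depth Mean extra reads (Poisson) beyond the first at a
#'   covered site.
#' @param lib_size_meanlog,lib_size_sdlog Log-normal parameters of the
#'   per-cell total UMI count.
#' @param nb_dispersion Negative-binomial dispersion (1/size) of per-gene
#'   UMI counts.
#' @return A list of class `observation_params`.
#' @export
observation_params <- function(breadth = 0.03, error_rate = 0.05,
                               swap_rate = 0.05, cells_per_strain = 4.83,
                               doublet_rate = 0.10, extra_depth = 0.2,
                               lib_size_meanlog = log(5000),
                               lib_size_sdlog = 0.4,
                               nb_dispersion = 0.2) {
  p <- list(breadth = breadth, error_rate = error_rate, swap_rate = swap_rate,
            cells_per_strain = cells_per_strain, doublet_rate = doublet_rate,
            extra_depth = extra_depth, lib_size_meanlog = lib_size_meanlog,
            lib_size_sdlog = lib_size_sdlog, nb_dispersion = nb_dispersion)
  rates <- c(breadth, error_rate, swap_rate, doublet_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(cells_per_strain > 0, extra_depth >= 0, nb_dispersion >= 0)
  class(p) <- "observation_params"
  p
}

#' Simulate the single-cell observation layer
#'
#' Draws barcodes over the strains of a panel (including doublets mixing two
#' distinct strains), sparse per-site allele read counts through the
#' error/swap channel, and a UMI expression matrix. Each read reports the
#' RM allele with probability (1 - s) * (1 - eps) + s * f when the cell's
#' true allele is RM (and (1 - s) * eps + s * f when BY), where f is the
#' pool RM frequency at the site.
#'
#' @param panel Segregant genotype matrix (strains x sites).
#' @param expression Strain mean log2 expression matrix (strains x genes)
#'   from [plant_architecture()]; may be NULL to skip the UMI layer.
#' @param obs An [observation_params()].
#' @param seed Integer seed.
#' @param n_cells Total barcodes; default `round(cells_per_strain * n_strains)`.
#' @return A list with `allele_counts` (tibble: barcode, site, rm, by),
#'   `umi` (sparse genes x barcodes dgCMatrix, or NULL) and `truth`
#'   (tibble: barcode, strain, strain2, is_doublet).
#' @export
simulate_cells <- function(panel, expression = NULL,
                           obs = observation_params(), seed = 1,
                           n_cells = NULL) {
  stopifnot(inherits(obs, "observation_params"), is.matrix(panel))
  n_strains <- nrow(panel)
  S <- ncol(panel)
  if (is.null(n_cells)) n_cells <- max(1L, round(obs$cells_per_strain * n_strains))
  f_pool <- colMeans(panel)
  withr::with_seed(seed, {
    barcodes <- sprintf("cell%05d", seq_len(n_cells))
    is_doublet <- stats::runif(n_cells) < obs$doublet_rate
    strain1 <- sample.int(n_strains, n_cells, replace = TRUE)
    strain2 <- rep(NA_integer_, n_cells)
    for (i in which(is_doublet)) {
      strain2[i] <- sample(setdiff(seq_len(n_strains), strain1[i]), 1)
    }

    counts <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      # a doublet droplet carries both constituent cells' transcripts:
      # coverage is drawn per constituent and reads keep their cell of origin
      constituents <- if (is_doublet[i]) c(strain1[i], strain2[i]) else strain1[i]
      site_of_read <- integer(0); origin <- integer(0)
      for (st in constituents) {
        covered <- which(stats::runif(S) < obs$breadth)
        if (length(covered) == 0) next
        depth <- 1L + stats::rpois(length(covered), obs$extra_depth)
        site_of_read <- c(site_of_read, rep(covered, depth))
        origin <- c(origin, rep(st, sum(depth)))
      }
      total <- length(site_of_read)
      if (total == 0) next
      truth_allele <- panel[cbind(origin, site_of_read)]
      p_rm <- (1 - obs$swap_rate) *
        ifelse(truth_allele == 1, 1 - obs$error_rate, obs$error_rate) +
        obs$swap_rate * f_pool[site_of_read]
      read_rm <- stats::runif(total) < p_rm
      rm_c <- tapply(as.integer(read_rm), site_of_read, sum)
      by_c <- tapply(as.integer(!read_rm), site_of_read, sum)
      counts[[i]] <- tibble::tibble(
        barcode = barcodes[i],
        site = as.integer(names(rm_c)),
        rm = as.integer(rm_c),
        by = as.integer(by_c)
      )
    }
    allele_counts <- dplyr::bind_rows(counts)
    if (nrow(allele_counts) == 0) {
      allele_counts <- tibble::tibble(barcode = character(), site = integer(),
                                      rm = integer(), by = integer())
    }

    umi <- NULL
    if (!is.null(expression)) {
      stopifnot(nrow(expression) == n_strains)
      n_genes <- ncol(expression)
      rates <- 2^expression
      lib <- stats::rlnorm(n_cells, obs$lib_size_meanlog, obs$lib_size_sdlog) +
        ifelse(is_doublet,
               stats::rlnorm(n_cells, obs$lib_size_meanlog, obs$lib_size_sdlog),
               0)
      size <- if (obs$nb_dispersion > 0) 1 / obs$nb_dispersion else Inf
      umi <- matrix(0L, nrow = n_genes, ncol = n_cells,
                    dimnames = list(colnames(expression), barcodes))
      for (i in seq_len(n_cells)) {
        r <- if (is_doublet[i]) {
          (rates[strain1[i], ] + rates[strain2[i], ]) / 2
        } else rates[strain1[i], ]
        mu <- lib[i] * r / sum(r)
        umi[, i] <- if (is.finite(size)) {
          stats::rnbinom(n_genes, mu = mu, size = size)
        } else stats::rpois(n_genes, mu)
      }
      umi <- methods::as(Matrix::Matrix(umi, sparse = TRUE), "CsparseMatrix")
    }

    truth <- tibble::tibble(
      barcode = barcodes,
      strain = rownames(panel)[strain1],
      strain2 = ifelse(is_doublet, rownames(panel)[strain2], NA_character_),
      is_doublet = is_doublet
    )
    list(allele_counts = allele_counts, umi = umi, truth = truth)
  })
}
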