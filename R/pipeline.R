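stage_names <- c("simulate", "genotype", "assign", "partition",
                 "map_qtl", "map_eqtl", "regulatory")

merge_defaults <- function(user, defaults, where) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown ", where, " option(s): ", paste(unknown, collapse = ", "))
  }
  # a NULL entry (e.g. a JSON null) means "use the default"
  user <- user[!vapply(user, is.null, logical(1))]
  utils::modifyList(defaults, user)
}

#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage's parameters with their package defaults, validates
#' them (unknown keys are errors, not warnings) and fixes the global seed.
#' Per-stage seeds are derived deterministically from the global seed, so a
#' config fully determines a run. The config round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param outdir Output directory; each stage writes under its own
#'   subdirectory.
#' @param seed Global integer seed.
#' @param sim,hmm,assign,reml,qtl,eqtl,arch Named lists overriding the
#'   stage defaults (see the source of this function for the full set).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, sim = list(), hmm = list(),
                            assign = list(), reml = list(), qtl = list(),
                            eqtl = list(), arch = list()) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    sim = merge_defaults(sim, list(
      n_strains = 100, n_sites = 500, n_chrom = 16, genome_bp = 12e6,
      cm_per_kb = 0.38, spacing_cm = NA,
      architecture = list(), observation = list()), "sim"),
    hmm = merge_defaults(hmm, list(
      estimate = TRUE, error_rate = 0.05, swap_rate = 0.05, rec_scale = 1,
      max_iter = 200, tol = 1e-6), "hmm"),
    assign = merge_defaults(assign, list(
      n_null = 100, fdr = 0.05, doublet_r2_max = 0.1), "assign"),
    reml = merge_defaults(reml, list(
      pc_var_threshold = 0.99, per_gene = FALSE), "reml"),
    qtl = merge_defaults(qtl, list(
      n_folds = 10, max_k_path = 50, max_k = NA), "qtl"),
    eqtl = merge_defaults(eqtl, list(lambda = NA, max_k = 10), "eqtl"),
    arch = merge_defaults(arch, list(
      window_bp = 25000, delta = 10, tau = NA, phi = 0.1,
      gap_penalty = 0.5, n_perm = 999), "arch")
  )
  cfg$sim$architecture <- merge_defaults(cfg$sim$architecture,
                                         as.list(unclass(architecture_spec())),
                                         "sim$architecture")
  cfg$sim$observation <- merge_defaults(cfg$sim$observation,
                                        as.list(unclass(observation_params())),
                                        "sim$observation")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj[setdiff(names(obj), character(0))])
}

stage_seed <- function(seed, stage) {
  idx <- match(stage, stage_names)
  as.integer((as.numeric(seed) * 48271 + idx * 1299709) %% 2147483647)
}

stage_files <- function(outdir) {
  list(
    simulate = file.path(outdir, "simulate",
                         c("map.tsv", "panel.tsv", "fitness.tsv", "genes.tsv",
                           "architecture.json", "allele_counts.tsv",
                           "truth.tsv", "umi/matrix.mtx", "umi/barcodes.tsv",
                           "umi/genes.tsv")),
    genotype = file.path(outdir, "genotype",
                         c("hmm_params.json", "posteriors.tsv")),
    assign = file.path(outdir, "assign",
                       c("assignments.tsv", "consensus_genotype.tsv",
                         "consensus_expression.tsv", "strains.tsv")),
    partition = file.path(outdir, "partition",
                          c("fitness_partition.json",
                            "expression_heritability.json")),
    map_qtl = file.path(outdir, "map_qtl", c("qtl.json", "cv.tsv")),
    map_eqtl = file.path(outdir, "map_eqtl",
                         c("eqtl.json", "eqtl_summary.tsv")),
    regulatory = file.path(outdir, "regulatory",
                           c("hotspots.tsv", "cis_trans.tsv", "matches.tsv",
                             "hotspot_qtl.json"))
  )
}

#' Run the full single-cell QTL/eQTL pipeline
#'
#' Executes the stages simulate, genotype, assign, partition, map_qtl,
#' map_eqtl and regulatory in order. Every stage reads only the previous
#' stages' serialized outputs and writes its own under
#' `<outdir>/<stage>/`, so the pipeline is re-entrant: a stage whose output
#' files already exist is skipped unless listed in `force` (downstream
#' stages of a forced stage are re-run too). A manifest recording files,
#' checksums, seeds and timings is written to `<outdir>/manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param force Character vector of stage names to re-run regardless of
#'   existing outputs, or TRUE for all.
#' @return Invisibly, the manifest tibble.
#' @export
run_pipeline <- function(config, force = character(0)) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- stage_files(outdir)
  if (isTRUE(force)) force <- stage_names
  # forcing a stage invalidates its descendants
  if (length(force) > 0) {
    first <- min(match(force, stage_names))
    force <- stage_names[first:length(stage_names)]
  }
  manifest <- list()
  for (stage in stage_names) {
    outputs <- files[[stage]]
    done <- all(file.exists(outputs))
    seed_s <- stage_seed(config$seed, stage)
    t0 <- Sys.time()
    ran <- FALSE
    if (!done || stage %in% force) {
      dir.create(file.path(outdir, stage), recursive = TRUE,
                 showWarnings = FALSE)
      run_stage(stage, config, outdir, seed_s)
      ran <- TRUE
    }
    manifest[[stage]] <- tibble::tibble(
      stage = stage, ran = ran, seed = seed_s,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      file = outputs,
      md5 = unname(tools::md5sum(outputs))
    )
  }
  manifest <- dplyr::bind_rows(manifest)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

run_stage <- function(stage, config, outdir, seed) {
  p <- function(...) file.path(outdir, ...)
  switch(stage,
    simulate = {
      s <- config$sim
      map <- sim_genetic_map(n_sites = s$n_sites, n_chrom = s$n_chrom,
                             genome_bp = s$genome_bp, cm_per_kb = s$cm_per_kb,
                             spacing_cm = if (is.na(s$spacing_cm)) NULL
                                          else s$spacing_cm,
                             seed = seed)
      panel <- simulate_cross(map, s$n_strains, seed = seed + 1L)
      arch <- do.call(architecture_spec, s$architecture)
      planted <- plant_architecture(panel, map, arch, seed = seed + 2L)
      obs <- do.call(observation_params, s$observation)
      cells <- simulate_cells(panel, planted$expression, obs, seed = seed + 3L)
      write_map_tsv(map, p("simulate", "map.tsv"))
      write_panel_tsv(panel, p("simulate", "panel.tsv"))
      write_fitness_tsv(planted$fitness, p("simulate", "fitness.tsv"))
      write_genes_tsv(planted$architecture$genes, p("simulate", "genes.tsv"))
      jsonlite::write_json(
        lapply(planted$architecture[c("qtl", "eqtl", "hotspots")],
               function(d) as.list(d)),
        p("simulate", "architecture.json"), auto_unbox = FALSE, digits = NA)
      write_allele_counts_tsv(cells$allele_counts,
                              p("simulate", "allele_counts.tsv"))
      readr::write_tsv(cells$truth, p("simulate", "truth.tsv"))
      write_umi_mtx(cells$umi, p("simulate", "umi"))
    },
    genotype = {
      map <- read_map_tsv(p("simulate", "map.tsv"))
      panel <- read_panel_tsv(p("simulate", "panel.tsv"))
      counts <- read_allele_counts_tsv(p("simulate", "allele_counts.tsv"))
      truth <- readr::read_tsv(p("simulate", "truth.tsv"),
                               show_col_types = FALSE)
      h <- config$hmm
      init <- hmm_params(error_rate = h$error_rate, swap_rate = h$swap_rate,
                         rec_scale = h$rec_scale)
      params <- if (isTRUE(h$estimate)) {
        estimate_hmm(counts, map, init, panel = panel, max_iter = h$max_iter,
                     tol = h$tol)$params
      } else init
      post <- suppressWarnings(
        posterior_genotypes(counts, map, params, barcodes = truth$barcode))
      jsonlite::write_json(params[c("error_rate", "swap_rate", "rec_scale",
                                    "init_rm")],
                           p("genotype", "hmm_params.json"),
                           auto_unbox = TRUE, digits = NA)
      post_df <- tibble::as_tibble(post$prob, .name_repair = "minimal")
      names(post_df) <- paste0("s", seq_len(ncol(post$prob)))
      post_df <- dplyr::bind_cols(tibble::tibble(barcode = post$barcodes),
                                  post_df)
      readr::write_tsv(post_df, p("genotype", "posteriors.tsv"))
    },
    assign = {
      map <- read_map_tsv(p("simulate", "map.tsv"))
      panel <- read_panel_tsv(p("simulate", "panel.tsv"))
      counts <- read_allele_counts_tsv(p("simulate", "allele_counts.tsv"))
      umi <- read_umi_mtx(p("simulate", "umi"))
      post_df <- readr::read_tsv(p("genotype", "posteriors.tsv"),
                                 show_col_types = FALSE)
      post <- as.matrix(post_df[-1])
      rownames(post) <- post_df$barcode
      a <- config$assign
      res <- assign_cells(post, panel, n_null = a$n_null, fdr = a$fdr,
                          counts = counts, doublet_r2_max = a$doublet_r2_max,
                          seed = seed, map = map)
      readr::write_tsv(res, p("assign", "assignments.tsv"))
      cons <- consensus_profiles(res, post, umi)
      write_panel_tsv(cons$genotype, p("assign", "consensus_genotype.tsv"))
      write_panel_tsv(t(cons$expression),
                      p("assign", "consensus_expression.tsv"))
      readr::write_tsv(cons$strains, p("assign", "strains.tsv"))
    },
    partition = {
      geno <- read_panel_tsv(p("assign", "consensus_genotype.tsv"))
      expr_raw <- t(read_panel_tsv(p("assign", "consensus_expression.tsv")))
      fitness <- read_fitness_tsv(p("simulate", "fitness.tsv"))
      expr <- normalize_expression(expr_raw)
      y <- fitness[rownames(geno)]
      part <- partition_fitness(y, geno, expr, se = FALSE)
      r <- config$reml
      herit <- expression_heritability(expr, geno,
                                       pc_var_threshold = r$pc_var_threshold,
                                       per_gene = r$per_gene)
      jsonlite::write_json(
        stats::setNames(as.list(part$fraction), part$component),
        p("partition", "fitness_partition.json"), auto_unbox = TRUE,
        digits = NA)
      jsonlite::write_json(list(overall = herit$overall, k = herit$k),
                           p("partition", "expression_heritability.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    map_qtl = {
      geno <- read_panel_tsv(p("assign", "consensus_genotype.tsv"))
      fitness <- read_fitness_tsv(p("simulate", "fitness.tsv"))
      q <- config$qtl
      fit <- map_qtl(geno, fitness[rownames(geno)], n_folds = q$n_folds,
                     max_k_path = q$max_k_path,
                     max_k = if (is.na(q$max_k)) NULL else q$max_k,
                     seed = seed)
      write_qtl_json(fit, p("map_qtl", "qtl.json"))
      readr::write_tsv(attr(fit, "cv"), p("map_qtl", "cv.tsv"))
    },
    map_eqtl = {
      geno <- read_panel_tsv(p("assign", "consensus_genotype.tsv"))
      expr_raw <- t(read_panel_tsv(p("assign", "consensus_expression.tsv")))
      expr <- normalize_expression(expr_raw)
      e <- config$eqtl
      eset <- map_eqtl(geno, expr,
                       lambda = if (is.na(e$lambda)) NULL else e$lambda,
                       max_k = e$max_k)
      write_qtl_json(eset, p("map_eqtl", "eqtl.json"))
      readr::write_tsv(eset$summary, p("map_eqtl", "eqtl_summary.tsv"))
    },
    regulatory = {
      map <- read_map_tsv(p("simulate", "map.tsv"))
      genes <- read_genes_tsv(p("simulate", "genes.tsv"))
      geno <- read_panel_tsv(p("assign", "consensus_genotype.tsv"))
      expr_raw <- t(read_panel_tsv(p("assign", "consensus_expression.tsv")))
      expr <- normalize_expression(expr_raw)
      eset <- read_qtl_json(p("map_eqtl", "eqtl.json"))
      qtl <- read_qtl_json(p("map_qtl", "qtl.json"))
      ar <- config$arch
      etidy <- tidy(eset)
      hots <- find_hotspots(etidy, map, window_bp = ar$window_bp)
      readr::write_tsv(tibble::as_tibble(hots), p("regulatory", "hotspots.tsv"))
      ct <- classify_cis_trans(etidy, genes, map)
      readr::write_tsv(ct, p("regulatory", "cis_trans.tsv"))

      matches <- list()
      if (nrow(qtl$sites) > 0) {
        ranks <- rank(abs(qtl$sites$beta))
        names(ranks) <- as.character(qtl$sites$site)
        genes_with <- eset$summary$gene[eset$summary$n_eqtl > 0]
        genes_with <- intersect(genes_with, colnames(expr))
        for (g in genes_with) {
          m <- match_qtl_eqtl(qtl, expr[, g], geno, map, eset$models[[g]],
                              delta = ar$delta,
                              tau = if (is.na(ar$tau)) NULL else ar$tau,
                              gap_penalty = ar$gap_penalty)
          pv <- if (nrow(m$pairs) > 0 && length(m$unmatched_qtl) >= nrow(m$pairs)) {
            rank_permutation_test(ranks[as.character(m$pairs$qtl_site)],
                                  ranks[as.character(m$unmatched_qtl)],
                                  n_perm = ar$n_perm, seed = seed)
          } else NA_real_
          matches[[g]] <- tibble::tibble(gene = g, n_matched = nrow(m$pairs),
                                         n_unmatched = length(m$unmatched_qtl),
                                         score = m$score, p_rank = pv)
        }
      }
      matches <- dplyr::bind_rows(matches)
      if (nrow(matches) == 0) {
        matches <- tibble::tibble(gene = character(), n_matched = integer(),
                                  n_unmatched = integer(), score = numeric(),
                                  p_rank = numeric())
      }
      readr::write_tsv(matches, p("regulatory", "matches.tsv"))
      hq <- tryCatch(
        hotspot_qtl_rank_correlation(qtl, hots, map, window_bp = ar$window_bp),
        error = function(e) tibble::tibble(rho = NA_real_, p_value = NA_real_,
                                           n = 0L),
        message = function(m) suppressMessages(
          tryCatch(hotspot_qtl_rank_correlation(qtl, hots, map,
                                                window_bp = ar$window_bp),
                   error = function(e) tibble::tibble(rho = NA_real_,
                                                      p_value = NA_real_,
                                                      n = 0L))))
      jsonlite::write_json(as.list(hq[1, ]), p("regulatory", "hotspot_qtl.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    },
    stop("unknown stage: ", stage)
  )
  invisible(NULL)
}
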