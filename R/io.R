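#' Read and write the pipeline's tabular formats
#'
#' All tabular artifacts are plain TSV with a header row; physical
#' coordinates are 1-based inclusive. Genotype panels are written strains x
#' sites with the strain id in the first column; allele counts as sparse
#' triplets (barcode, site, rm, by); expression as Matrix Market triplets
#' alongside barcode and gene lists. Every writer/reader pair round-trips
#' losslessly.
#'
#' @param panel Strains x sites numeric matrix.
#' @param path Output file path.
#' @return `read_panel_tsv()` returns the matrix; writers return the path
#'   invisibly.
#' @name io_tsv
NULL

#' @rdname io_tsv
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(is.matrix(panel))
  df <- tibble::as_tibble(panel, .name_repair = "minimal")
  names(df) <- colnames(panel) %||% paste0("s", seq_len(ncol(panel)))
  df <- dplyr::bind_cols(tibble::tibble(strain = rownames(panel) %||%
                                          paste0("strain", seq_len(nrow(panel)))),
                         df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io_tsv
#' @param counts Allele-count tibble (`barcode`, `site`, `rm`, `by`).
#' @export
write_allele_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts[c("barcode", "site", "rm", "by")], path)
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_allele_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    barcode = readr::col_character(), site = readr::col_integer(),
    rm = readr::col_integer(), by = readr::col_integer()))
}

#' @rdname io_tsv
#' @param map A `genetic_map`.
#' @export
write_map_tsv <- function(map, path) {
  readr::write_tsv(map[c("site", "chrom", "pos", "cm")], path)
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_map_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    site = readr::col_integer(), chrom = readr::col_character(),
    pos = readr::col_integer(), cm = readr::col_double()))
  genetic_map(df[c("chrom", "pos", "cm")])
}

#' @rdname io_tsv
#' @param fitness Named numeric vector.
#' @export
write_fitness_tsv <- function(fitness, path) {
  readr::write_tsv(tibble::tibble(strain = names(fitness),
                                  fitness = unname(fitness)), path)
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_fitness_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    strain = readr::col_character(), fitness = readr::col_double()))
  stats::setNames(df$fitness, df$strain)
}

#' Write / read a UMI matrix as Matrix Market triplets
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `genes.tsv` (CellRanger layout)
#' under `dir`. The reader validates that the matrix header dimensions agree
#' with the barcode and gene lists and that every triplet lies within the
#' declared dimensions, reporting the offending line on failure.
#'
#' @param umi Genes x cells matrix (sparse or dense).
#' @param dir Directory for the three files.
#' @return `read_umi_mtx()` returns a sparse dgCMatrix with dimnames.
#' @export
write_umi_mtx <- function(umi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(Matrix::Matrix(umi, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(umi) %||% paste0("cell", seq_len(ncol(umi))),
             file.path(dir, "barcodes.tsv"))
  writeLines(rownames(umi) %||% paste0("gene", seq_len(nrow(umi))),
             file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' @rdname write_umi_mtx
#' @export
read_umi_mtx <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  lines <- readLines(mtx_path)
  body <- which(!startsWith(lines, "%"))
  if (length(body) == 0) stop("no header in ", mtx_path)
  hdr_line <- body[1]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[hdr_line]),
                                              "\\s+")[[1]]))
  if (length(hdr) != 3 || anyNA(hdr)) {
    stop("malformed MTX size header at line ", hdr_line, " of ", mtx_path)
  }
  if (hdr[1] != length(genes)) {
    stop("MTX header at line ", hdr_line, " declares ", hdr[1],
         " rows but genes.tsv lists ", length(genes))
  }
  if (hdr[2] != length(barcodes)) {
    stop("MTX header at line ", hdr_line, " declares ", hdr[2],
         " columns but barcodes.tsv lists ", length(barcodes))
  }
  for (li in body[-1]) {
    trip <- suppressWarnings(as.numeric(strsplit(trimws(lines[li]),
                                                 "\\s+")[[1]]))
    if (length(trip) != 3 || anyNA(trip)) {
      stop("malformed MTX triplet at line ", li, " of ", mtx_path)
    }
    if (trip[1] < 1 || trip[1] > hdr[1] || trip[2] < 1 || trip[2] > hdr[2]) {
      stop("MTX triplet at line ", li, " is outside the declared dimensions")
    }
  }
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write / read a BED-like gene annotation table
#'
#' Columns `gene`, `chrom`, `start`, `end`, `strand`; coordinates 1-based
#' inclusive (stated in the file header comment). Files produced with
#' 0-based starts can be read back with `zero_based = TRUE`, which shifts
#' starts up by one.
#'
#' @param genes Gene annotation tibble.
#' @param path File path.
#' @param zero_based Input uses 0-based start coordinates.
#' @export
write_genes_tsv <- function(genes, path) {
  con <- file(path, "w")
  writeLines("# coordinates: 1-based inclusive", con)
  close(con)
  readr::write_tsv(genes[c("gene", "chrom", "start", "end", "strand")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_genes_tsv
#' @export
read_genes_tsv <- function(path, zero_based = FALSE) {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    strand = readr::col_character()))
  if (zero_based) df$start <- df$start + 1L
  df
}

#' Serialize a QTL model (or eQTL set) to JSON and back
#'
#' @param fit A `qtl_fit` or `eqtl_set`.
#' @param path JSON file path.
#' @export
write_qtl_json <- function(fit, path) {
  to_list <- function(m) {
    list(sites = m$sites$site, locus = m$sites$locus, beta = m$sites$beta,
         intercept = m$intercept, rss = m$rss, lambda = m$lambda,
         objective = m$objective, r2 = m$r2, n = m$n)
  }
  obj <- if (inherits(fit, "eqtl_set")) {
    list(kind = "eqtl_set", lambda = fit$lambda, n = fit$n,
         models = lapply(fit$models, to_list))
  } else {
    c(list(kind = "qtl_fit"), to_list(fit))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qtl_json
#' @export
read_qtl_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_list <- function(l) {
    rss0 <- if (l$r2 < 1) l$rss / (1 - l$r2) else l$rss
    fit <- new_qtl_fit(as.integer(unlist(l$sites)), as.numeric(unlist(l$beta)),
                       l$intercept, l$rss, l$lambda, rss0, l$n,
                       locus_names = NULL)
    if (nrow(fit$sites) > 0) fit$sites$locus <- as.character(unlist(l$locus))
    fit
  }
  if (identical(obj$kind, "eqtl_set")) {
    models <- lapply(obj$models, from_list)
    structure(list(models = models,
                   summary = tibble::tibble(
                     gene = names(models),
                     n_eqtl = vapply(models, function(m) nrow(m$sites),
                                     integer(1)),
                     r2 = vapply(models, function(m) m$r2, numeric(1))),
                   lambda = obj$lambda, n = obj$n), class = "eqtl_set")
  } else {
    from_list(obj)
  }
}
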