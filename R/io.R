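#' Read a UMI count matrix
#'
#' Accepts Matrix Market coordinate format with companion `genes.tsv` /
#' `barcodes.tsv` files (genes are rows, cells are columns), or a dense TSV
#' with gene ids in the first column and cell ids in the header.  Entries
#' must be nonnegative integers.
#'
#' @param path path to a `.mtx` file (companions found alongside) or a TSV.
#' @return sparse genes x cells dgCMatrix with dimnames.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    dir <- dirname(path)
    genes <- read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[, 1]
    cells <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[, 1]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("gene/cell id files do not match matrix dimensions")
    dimnames(m) <- list(genes, cells)
  } else {
    d <- read.delim(path, row.names = 1, check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(d), sparse = TRUE)
  }
  if (nrow(m) == 0) stop("empty matrix: 0 genes")
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
  x <- m@x
  if (any(x < 0)) stop("negative entries in UMI matrix")
  if (any(x != round(x))) stop("non-integer entries in UMI matrix")
  m
}

#' Write a UMI count matrix
#'
#' Writes Matrix Market coordinate format plus `genes.tsv` and
#' `barcodes.tsv` companions.
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the `.mtx` file.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(methods::as(counts, "CsparseMatrix"),
                              "generalMatrix"), path)
  write.table(rownames(counts), file.path(dir, "genes.tsv"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(colnames(counts), file.path(dir, "barcodes.tsv"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Pipeline configuration
#'
#' Bundles the stage parameters and either a simulation request or input
#' paths.  All outputs record the seed.
#'
#' @param simulate `NULL`, or a list passed to [sim_clock_panel()]
#'   (`n_genes`, `size_scale`, `bad_cells`, `empty_wells`).
#' @param matrix,meta,clusters input paths (ignored when `simulate` is set).
#' @param qc a [qc_thresholds()].
#' @param rhythm a [rhythm_params()].
#' @param rhythm_genes optional gene subset for rhythm testing.
#' @param marker_alpha,marker_fc_min marker gates.
#' @param rules identity rule list.
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), matrix = NULL, meta = NULL,
                            clusters = NULL, qc = qc_thresholds(),
                            rhythm = rhythm_params(), rhythm_genes = NULL,
                            marker_alpha = 0.05, marker_fc_min = 1.25,
                            rules = default_clock_rules(), seed = 1L) {
  if (!length(simulate)) {
    for (p in c(matrix, meta, clusters))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(simulate = simulate, matrix = matrix, meta = meta,
                 clusters = clusters, qc = qc, rhythm = rhythm,
                 rhythm_genes = rhythm_genes, marker_alpha = marker_alpha,
                 marker_fc_min = marker_fc_min, rules = rules,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' simulate (or load) -> QC -> TP10K -> rhythm -> markers -> annotate, writing
#' every stage's table under `outdir` together with a JSON manifest (inputs,
#' parameters, seed, per-file MD5 checksums).  Runs are deterministic given
#' the configuration.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  if (length(config$simulate)) {
    sim <- do.call(sim_clock_panel,
                   c(list(seed = config$seed), config$simulate))
    counts <- sim$counts; meta <- sim$meta; clusters <- sim$clusters
    files["matrix"] <- write_count_matrix(counts, file.path(outdir, "sim"))
    files["meta"] <- write_tsv(meta, file.path(outdir, "sim", "meta.tsv"))
    files["clusters"] <- write_tsv(clusters,
                                   file.path(outdir, "sim", "clusters.tsv"))
  } else {
    counts <- read_count_matrix(config$matrix)
    meta <- read.delim(config$meta, stringsAsFactors = FALSE)
    clusters <- read.delim(config$clusters, stringsAsFactors = FALSE)
  }
  missing <- setdiff(colnames(counts), meta$cell)
  if (length(missing))
    stop("cell(s) in matrix but not metadata: ",
         paste(head(missing, 5), collapse = ", "))
  missing <- setdiff(colnames(counts), clusters$cell)
  if (length(missing))
    stop("cell(s) without cluster assignment: ",
         paste(head(missing, 5), collapse = ", "))

  qc <- filter_cells(counts, config$qc)
  files["qc_report"] <- write_tsv(qc$report,
                                  file.path(outdir, "qc_report.tsv"))
  expr <- to_tp10k(qc$counts)
  kept <- colnames(expr)
  meta_k <- meta[meta$cell %in% kept, , drop = FALSE]
  clust_k <- clusters[clusters$cell %in% kept, , drop = FALSE]

  rec <- call_cyclers(expr, meta_k, clust_k, config$rhythm,
                      genes = config$rhythm_genes)
  files["rhythm"] <- write_tsv(rec, file.path(outdir, "rhythm.tsv"))
  summ <- aggregate(is_cycler ~ cluster + condition, rec, sum)
  names(summ)[3] <- "n_cyclers"
  files["rhythm_summary"] <- write_tsv(summ,
                                       file.path(outdir,
                                                 "rhythm_summary.tsv"))

  mk <- find_markers(expr, clust_k, alpha = config$marker_alpha,
                     fc_min = config$marker_fc_min)
  files["markers"] <- write_tsv(mk, file.path(outdir, "markers.tsv"))

  rule_genes <- unique(unlist(lapply(config$rules, function(r)
    c(r$present, r$absent, r$present_any))))
  rule_genes <- intersect(rule_genes, rownames(expr))
  dot <- dot_stats(expr, clust_k, rule_genes)
  ld_cells <- meta_k$cell[meta_k$condition == "LD"]
  dot_ld <- if (length(ld_cells))
    dot_stats(expr[, colnames(expr) %in% ld_cells, drop = FALSE],
              clust_k[clust_k$cell %in% ld_cells, , drop = FALSE],
              rule_genes) else NULL
  prof <- cluster_profiles(expr, meta_k, clust_k)
  calls <- annotate_clusters(dot, prof, rules = config$rules,
                             dot_ld = dot_ld)
  files["identities"] <- write_tsv(calls,
                                   file.path(outdir, "identities.tsv"))

  manifest <- list(
    seed = config$seed,
    parameters = list(qc = unclass(config$qc),
                      rhythm = unclass(config$rhythm),
                      marker_alpha = config$marker_alpha,
                      marker_fc_min = config$marker_fc_min),
    n_cells_input = ncol(counts), n_cells_pass = length(kept),
    stages = names(files),
    files = lapply(setNames(names(files), names(files)), function(k)
      list(path = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]])))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
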