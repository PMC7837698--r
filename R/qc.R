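#' Quality-control thresholds
#'
#' Three-part cell filter: detected genes (a gene counts as detected with at
#' least one UMI), total UMIs, and expression entropy.  A cell passes when all
#' values lie inside the closed intervals; the failing sides are exclusive
#' ("fewer than" / "more than" / "smaller than"), so boundary values are kept.
#'
#' @param min_genes,max_genes detected-gene range (defaults 1000-6000).
#' @param min_umi,max_umi total-UMI range (defaults 6000-75000).
#' @param min_entropy minimum expression entropy in nats (default 5.5).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 1000, max_genes = 6000,
                          min_umi = 6000, max_umi = 75000,
                          min_entropy = 5.5) {
  stopifnot(min_genes < max_genes, min_umi < max_umi, min_entropy >= 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umi = min_umi, max_umi = max_umi,
                 min_entropy = min_entropy),
            class = "qc_thresholds")
}

#' Expression entropy of a single cell
#'
#' Shannon entropy, in nats, of the within-cell gene frequency distribution:
#' `-sum(p_g * ln p_g)` over genes with positive counts, `p_g` the gene's
#' share of the cell's UMIs.  The entropy is `ln G` for `G` equally expressed
#' genes and 0 for a single-gene cell, so a 5.5-nat cutoff separates cells
#' with thousands of detected genes (~7.9 nats at 2,600 genes) from
#' empty-well-like cells.  An all-zero cell returns 0 (and fails QC on the
#' UMI criterion downstream).
#'
#' @param counts nonnegative count vector for one cell.
#' @return entropy in nats.
#' @export
cell_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# vectorized per-cell QC metrics on a sparse genes x cells matrix
qc_metrics <- function(counts) {
  counts <- methods::as(counts, "CsparseMatrix")
  tot <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  x <- counts@x
  j <- rep.int(seq_len(ncol(counts)), diff(counts@p))
  xlx <- rep(0, ncol(counts))
  pos <- x > 0
  sums <- tapply(x[pos] * log(x[pos]), j[pos], sum)
  xlx[as.integer(names(sums))] <- sums
  ent <- ifelse(tot > 0, log(pmax(tot, 1)) - xlx / pmax(tot, 1), 0)
  data.frame(cell = colnames(counts), n_genes = as.integer(ngene),
             n_umi = as.integer(round(tot)), entropy = ent,
             stringsAsFactors = FALSE)
}

#' Filter low-quality cells
#'
#' @param counts genes x cells UMI count matrix.
#' @param thresholds a [qc_thresholds()].
#' @return list with `counts` (cells passing all three criteria) and
#'   `report`, a per-cell data.frame with the metrics, per-criterion pass
#'   flags and the overall verdict.  Filtering is idempotent.
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"), ncol(counts) > 0)
  m <- qc_metrics(counts)
  m$pass_genes <- m$n_genes >= thresholds$min_genes &
                  m$n_genes <= thresholds$max_genes
  m$pass_umi <- m$n_umi >= thresholds$min_umi &
                m$n_umi <= thresholds$max_umi
  m$pass_entropy <- m$entropy >= thresholds$min_entropy
  m$pass <- m$pass_genes & m$pass_umi & m$pass_entropy
  if (!any(m$pass)) warning("no cells pass QC")
  list(counts = counts[, m$pass, drop = FALSE], report = m)
}

#' TP10K normalization
#'
#' Transcripts per 10,000: each cell's counts divided by its total UMIs and
#' multiplied by 10^4, so columns sum to 10^4.
#'
#' @param counts genes x cells count matrix with positive cell totals
#'   (run [filter_cells()] first).
#' @return sparse matrix on the TP10K scale, attribute `scale = "tp10k"`.
#' @export
to_tp10k <- function(counts) {
  tot <- Matrix::colSums(counts)
  if (any(tot <= 0))
    stop("zero-total cell(s): ",
         paste(head(colnames(counts)[tot <= 0], 5), collapse = ", "))
  out <- counts %*% Matrix::Diagonal(x = 1e4 / tot)
  dimnames(out) <- dimnames(counts)
  attr(out, "scale") <- "tp10k"
  out
}

#' Pseudo-bulk reconstruction
#'
#' Pools single cells into group mean profiles, e.g. by condition and
#' replicate, reconstructing bulk-like samples from the single-cell data.
#'
#' @param expr genes x cells expression matrix (typically TP10K).
#' @param meta per-cell metadata with a `cell` column.
#' @param group_by metadata column names defining the groups.
#' @return list: `mean` (genes x groups matrix) and `n_cells` (named counts).
#' @export
pseudobulk <- function(expr, meta, group_by = c("condition", "replicate")) {
  stopifnot(all(group_by %in% names(meta)))
  meta <- meta[match(colnames(expr), meta$cell), , drop = FALSE]
  if (anyNA(meta$cell)) stop("cells missing from metadata")
  key <- interaction(meta[group_by], drop = TRUE, sep = "_")
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(key),
                              x = 1, dims = c(length(key), nlevels(key)),
                              dimnames = list(NULL, levels(key)))
  n <- Matrix::colSums(ind)
  mean_mat <- as.matrix(expr %*% ind %*% Matrix::Diagonal(x = 1 / n))
  dimnames(mean_mat) <- list(rownames(expr), levels(key))
  list(mean = mean_mat, n_cells = setNames(as.integer(n), levels(key)))
}

#' Correlation of two mean expression profiles
#'
#' Pearson correlation, by default on the `ln(TP10K + 1)` scale, used to
#' compare cluster or pseudo-bulk profiles.
#'
#' @param a,b numeric profiles over the same gene universe.
#' @param log_transform apply `log1p` first (default `TRUE`).
#' @return Pearson r, or `NA` with a warning if either profile has zero
#'   variance.
#' @export
profile_correlation <- function(a, b, log_transform = TRUE) {
  stopifnot(length(a) == length(b))
  if (log_transform) { a <- log1p(a); b <- log1p(b) }
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance profile; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}
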