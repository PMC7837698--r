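#' One-vs-rest marker detection
#'
#' For every gene and cluster, compares expression in the cluster against all
#' remaining cells with a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction) on `ln(TP10K + 1)` values, Bonferroni
#' correction over the genes tested within the cluster, and a natural-scale
#' fold-change gate with a pseudocount.  A marker is significant when
#' `p_adj < alpha` and fold change `> fc_min` (both strict).
#'
#' The reference study fitted a covariate-adjusted negative-binomial model
#' for this step; the rank-sum test used here is a robust covariate-free
#' substitute whose target is recovery of truly enriched genes rather than
#' coefficient replication.
#'
#' @param expr genes x cells TP10K matrix.
#' @param clusters named cluster vector (cell -> cluster) or data.frame with
#'   `cell`, `cluster`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param fc_min fold-change cutoff (default 1.25, strict).
#' @param pseudocount added to both means before the ratio (default 0.1
#'   TP10K).
#' @param min_pct detectability floor: a gene enters a cluster's test (and
#'   its Bonferroni family) only when expressed in at least this fraction of
#'   the in-cluster or of the out-of-cluster cells (default 0.1).  The
#'   normal approximation to the rank-sum null is badly anticonservative for
#'   genes expressed in a handful of cells, so near-undetected genes are not
#'   tested.
#' @return data.frame, one row per tested gene x cluster: `p`, `p_adj`,
#'   `fold_change`, `log2_fold_change`, `pct_in`, `pct_out`, `mean_in`,
#'   `mean_out`, `significant`.
#' @export
find_markers <- function(expr, clusters, alpha = 0.05, fc_min = 1.25,
                         pseudocount = 0.1, min_pct = 0.1) {
  labs <- if (is.data.frame(clusters))
    setNames(clusters$cluster, clusters$cell) else clusters
  labs <- labs[colnames(expr)]
  if (anyNA(labs)) stop("cells missing from cluster assignment")
  cl_ids <- sort(unique(labs))
  if (length(cl_ids) < 2) stop("need >= 2 clusters")
  if (min(table(labs)) < 3) stop("need >= 3 cells per cluster")

  keep <- Matrix::rowSums(expr > 0) > 0
  X <- as.matrix(expr[keep, , drop = FALSE])
  L <- log1p(X)
  n <- ncol(L)
  G <- nrow(L)

  rk <- t(apply(L, 1, rank))
  tie_term <- apply(L, 1, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })

  pos <- X > 0
  out <- vector("list", length(cl_ids))
  for (ci in seq_along(cl_ids)) {
    inn <- labs == cl_ids[ci]
    n1 <- sum(inn); n2 <- n - n1
    pct_in <- rowMeans(pos[, inn, drop = FALSE])
    pct_out <- rowMeans(pos[, !inn, drop = FALSE])
    tested <- pct_in >= min_pct | pct_out >= min_pct
    m <- sum(tested)
    R1 <- rowSums(rk[, inn, drop = FALSE])
    U <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    z <- (U - mu) / pmax(sig, .Machine$double.eps)
    p <- 2 * pnorm(-abs(z))
    p_adj <- pmin(1, p * m)
    mean_in <- rowMeans(X[, inn, drop = FALSE])
    mean_out <- rowMeans(X[, !inn, drop = FALSE])
    fc <- (mean_in + pseudocount) / (mean_out + pseudocount)
    out[[ci]] <- data.frame(
      gene = rownames(X), cluster = cl_ids[ci],
      p = p, p_adj = p_adj,
      fold_change = fc, log2_fold_change = log2(fc),
      pct_in = pct_in, pct_out = pct_out,
      mean_in = mean_in, mean_out = mean_out,
      significant = p_adj < alpha & fc > fc_min,
      stringsAsFactors = FALSE)[tested, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dot-plot summary statistics
#'
#' Per gene and cluster: the fraction of cells with nonzero counts (dot size)
#' and the mean TP10K expression (dot color), the numbers behind a standard
#' marker dot plot.
#'
#' @param expr genes x cells TP10K matrix.
#' @param clusters named cluster vector or data.frame with `cell`, `cluster`.
#' @param genes genes to summarize; unknown genes are reported in the
#'   `"unmatched"` attribute with a warning, not an error.
#' @return data.frame `gene`, `cluster`, `pct`, `mean_tp10k`.
#' @export
dot_stats <- function(expr, clusters, genes) {
  labs <- if (is.data.frame(clusters))
    setNames(clusters$cluster, clusters$cell) else clusters
  labs <- labs[colnames(expr)]
  unmatched <- setdiff(genes, rownames(expr))
  if (length(unmatched))
    warning("genes not in matrix: ", paste(unmatched, collapse = ", "))
  genes <- intersect(genes, rownames(expr))
  cl_ids <- sort(unique(labs))
  X <- as.matrix(expr[genes, , drop = FALSE])
  res <- do.call(rbind, lapply(cl_ids, function(cl) {
    inn <- labs == cl
    data.frame(gene = genes, cluster = cl,
               pct = rowMeans(X[, inn, drop = FALSE] > 0),
               mean_tp10k = rowMeans(X[, inn, drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "unmatched") <- unmatched
  res
}
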