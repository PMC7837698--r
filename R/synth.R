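#' Simulation design for a circadian single-cell time course
#'
#' Describes the sampling design the simulator emulates: clusters of unequal
#' size sampled at equally spaced timepoints around the clock under one or two
#' lighting conditions with replicate plates.  Defaults reproduce a 6-timepoint
#' x LD/DD x 2-replicate CEL-Seq2-style design with roughly 20,000 UMIs and
#' 2,600 detected genes per cell.
#'
#' @param n_clusters number of cell clusters.
#' @param cluster_sizes integer vector, one entry per cluster: cells per
#'   cluster in each timepoint x condition x replicate group.
#' @param timepoints sampling times in hours, strictly increasing and equally
#'   spaced within `[0, 24)`.  ZT and CT share this numeric axis; the
#'   condition flag distinguishes them.
#' @param conditions subset of `c("LD", "DD")`.
#' @param n_replicates replicate plates per condition.
#' @param n_genes number of genes in the matrix.
#' @param baseline_mean expected UMIs per background gene in an average cell;
#'   together with `n_genes` this sets the mean library size
#'   (`baseline_mean * n_genes`, 20,000 at the defaults).
#' @param dispersion negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param library_size_cv coefficient of variation of the lognormal
#'   cell-to-cell library-size factor.
#' @param gene_sd_log sdlog of the lognormal spread of background gene
#'   abundances; 1.9 yields ~2,600 detected genes per cell at the defaults.
#' @param seed integer seed; identical seeds give bit-identical simulations.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_clusters = 3,
                       cluster_sizes = rep(20, n_clusters),
                       timepoints = c(2, 6, 10, 14, 18, 22),
                       conditions = c("LD", "DD"),
                       n_replicates = 2,
                       n_genes = 5000,
                       baseline_mean = 4,
                       dispersion = 0.25,
                       library_size_cv = 0.35,
                       gene_sd_log = 1.9,
                       seed = 1L) {
  stopifnot(n_clusters >= 1, length(cluster_sizes) == n_clusters,
            all(cluster_sizes >= 1), n_genes >= 10,
            baseline_mean > 0, dispersion >= 0, library_size_cv >= 0,
            length(timepoints) >= 2)
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (length(timepoints) > 2 &&
      max(abs(diff(diff(timepoints)))) > 1e-8)
    stop("timepoints must be equally spaced")
  if (any(timepoints < 0 | timepoints >= 24))
    stop("timepoints must lie in [0, 24)")
  conditions <- match.arg(conditions, c("LD", "DD"), several.ok = TRUE)
  structure(list(n_clusters = n_clusters,
                 cluster_sizes = as.integer(cluster_sizes),
                 timepoints = timepoints,
                 conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 n_genes = as.integer(n_genes),
                 baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 library_size_cv = library_size_cv,
                 gene_sd_log = gene_sd_log,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Planted cycling gene
#'
#' Ground-truth specification of one cycling transcript in one cluster.  The
#' mean TP10K profile is `baseline * (1 + a * cos(2*pi*(t - peak_phase)/24))`
#' with `a = (fold_amplitude - 1)/(fold_amplitude + 1)`, so the peak/trough
#' ratio of the noise-free profile equals `fold_amplitude` exactly and the
#' mesor equals `baseline`.
#'
#' @param gene gene identifier.
#' @param cluster cluster identifier the rhythm is planted in.
#' @param condition_behavior one of `"both"`, `"LD_only"`, `"DD_only"`,
#'   `"antiphase_in_DD"` (peak shifted by 12 h in DD, the DN2 signature).
#' @param fold_amplitude peak/trough ratio of the mean profile, `>= 1`.
#' @param peak_phase peak time in hours, in `[0, 24)`.
#' @param baseline mesor of the mean profile on the TP10K scale.
#' @return one-row data.frame.
#' @export
planted_cycler <- function(gene, cluster,
                           condition_behavior = c("both", "LD_only",
                                                  "DD_only", "antiphase_in_DD"),
                           fold_amplitude, peak_phase, baseline) {
  condition_behavior <- match.arg(condition_behavior)
  if (fold_amplitude < 1) stop("fold_amplitude must be >= 1")
  if (peak_phase < 0 || peak_phase >= 24) stop("peak_phase must be in [0, 24)")
  if (baseline <= 0) stop("baseline must be positive")
  data.frame(gene = gene, cluster = as.character(cluster),
             condition_behavior = condition_behavior,
             fold_amplitude = fold_amplitude, peak_phase = peak_phase,
             baseline = baseline, stringsAsFactors = FALSE)
}

#' Planted cluster marker
#'
#' @param gene gene identifier.
#' @param clusters character vector of clusters the marker is enriched in.
#' @param fold_enrichment mean enrichment of expressing in-cluster cells over
#'   the out-of-cluster baseline, `> 1`.
#' @param expressing_fraction fraction of in-cluster cells expressing the
#'   marker, in `(0, 1]`.
#' @param baseline out-of-cluster mean on the TP10K scale (low by default so
#'   markers are near-absent elsewhere).
#' @return one-row data.frame (`clusters` is a list column).
#' @export
planted_marker <- function(gene, clusters, fold_enrichment,
                           expressing_fraction = 0.9, baseline = 0.1) {
  if (fold_enrichment <= 1) stop("fold_enrichment must be > 1")
  if (expressing_fraction <= 0 || expressing_fraction > 1)
    stop("expressing_fraction must be in (0, 1]")
  out <- data.frame(gene = gene, fold_enrichment = fold_enrichment,
                    expressing_fraction = expressing_fraction,
                    baseline = baseline, stringsAsFactors = FALSE)
  out$clusters <- list(as.character(clusters))
  out
}

#' Noise-free mean profile of a planted cycler
#'
#' Evaluates the cosine mean function of a [planted_cycler()] at given
#' timepoints under a condition, on the TP10K scale (before the per-cell
#' normalization that the finite transcriptome imposes).
#'
#' @param cycler one row of [planted_cycler()] output.
#' @param timepoints hours.
#' @param condition `"LD"` or `"DD"`.
#' @return numeric vector of mean TP10K values.
#' @export
planted_mean_profile <- function(cycler, timepoints, condition = "LD") {
  stopifnot(nrow(cycler) == 1)
  cycler_mean_at(cycler, timepoints, condition)
}

cycling_multiplier <- function(t_h, fold, peak_phase) {
  a <- (fold - 1) / (fold + 1)
  1 + a * cos(2 * pi * (t_h - peak_phase) / 24)
}

# TP10K-scale mean of one planted cycler at time t under a condition
cycler_mean_at <- function(cyc, t_h, condition) {
  phase <- cyc$peak_phase
  flat <- FALSE
  if (condition == "LD" && cyc$condition_behavior == "DD_only") flat <- TRUE
  if (condition == "DD") {
    if (cyc$condition_behavior == "LD_only") flat <- TRUE
    if (cyc$condition_behavior == "antiphase_in_DD")
      phase <- (phase + 12) %% 24
  }
  if (flat) rep(cyc$baseline, length(t_h))
  else cyc$baseline * cycling_multiplier(t_h, cyc$fold_amplitude, phase)
}

#' Simulate a circadian single-cell UMI count matrix with known ground truth
#'
#' Draws negative-binomial UMI counts for a design of clusters x timepoints x
#' conditions x replicates.  Background gene abundances are lognormal and
#' rescaled so that each cluster's expected TP10K profile sums to ~10^4; on
#' top of that, planted markers multiply the mean in their clusters and
#' planted cyclers impose cosine mean profiles with an exact peak/trough
#' fold.  Library sizes are lognormal around `baseline_mean * n_genes` UMIs.
#' Everything planted is recorded in a ground-truth ledger.
#'
#' @param design a [sim_design()].
#' @param cyclers data.frame of [planted_cycler()] rows (or `NULL`).
#' @param markers data.frame of [planted_marker()] rows (or `NULL`).
#' @param identities named character vector mapping cluster ids to anatomical
#'   labels (ground truth for annotation tests), or `NULL`.
#' @param bad_cells named integer vector of planted QC violators, e.g.
#'   `c(low_genes = 2, low_umi = 2, high_umi = 2, low_entropy = 2,
#'   high_genes = 2)` (`high_genes` requires `n_genes > 6000`).
#' @return a list with components `counts` (sparse genes x cells dgCMatrix),
#'   `meta` (per-cell data.frame: `cell`, `timepoint_h`, `condition`,
#'   `replicate`, `batch`, `role`), `clusters` (data.frame `cell`, `cluster`),
#'   and `truth` (list: `cell_labels`, `cyclers`, `markers`, `identities`,
#'   `bad_cells`, `empty_wells`).
#' @export
simulate_scdata <- function(design, cyclers = NULL, markers = NULL,
                            identities = NULL, bad_cells = NULL) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  cl_ids <- sprintf("cl%02d", seq_len(design$n_clusters))
  if (!is.null(identities)) {
    if (!all(names(identities) %in% cl_ids))
      stop("identities refer to unknown clusters: ",
           paste(setdiff(names(identities), cl_ids), collapse = ", "))
  }
  special <- unique(c(if (!is.null(cyclers)) cyclers$gene,
                      if (!is.null(markers)) markers$gene))
  if (length(special) > design$n_genes)
    stop("more special genes than n_genes")
  if (!is.null(cyclers) && !all(cyclers$cluster %in% cl_ids))
    stop("cycler assigned to nonexistent cluster: ",
         paste(setdiff(cyclers$cluster, cl_ids), collapse = ", "))
  if (!is.null(cyclers) && any(cyclers$fold_amplitude < 1))
    stop("fold_amplitude must be >= 1")
  if (!is.null(markers) && !all(unlist(markers$clusters) %in% cl_ids))
    stop("marker assigned to nonexistent cluster")

  n_bg <- design$n_genes - length(special)
  genes <- c(special, sprintf("g%05d", seq_len(n_bg)))

  # background abundances on an approximate TP10K scale
  w_bg <- rlnorm(n_bg, meanlog = 0, sdlog = design$gene_sd_log)
  special_mass <- 0
  if (!is.null(cyclers)) special_mass <- special_mass + sum(cyclers$baseline)
  if (!is.null(markers)) special_mass <- special_mass + sum(markers$baseline)
  w_bg <- w_bg / sum(w_bg) * max(1e4 - special_mass, 0.5e4)
  base_w <- c(rep(0, length(special)), w_bg)
  names(base_w) <- genes
  # special genes sit at a low out-of-cluster baseline everywhere; the
  # planted signal raises them only in their own clusters
  if (!is.null(markers)) base_w[markers$gene] <- markers$baseline
  if (!is.null(cyclers))
    base_w[cyclers$gene] <- pmax(base_w[cyclers$gene], 0.1)

  mean_lib <- design$baseline_mean * design$n_genes
  sdl <- sqrt(log(1 + design$library_size_cv^2))
  size_nb <- if (design$dispersion > 0) 1 / design$dispersion else Inf

  draw_counts <- function(mu_mat) {
    n <- length(mu_mat)
    x <- if (is.finite(size_nb)) rnbinom(n, size = size_nb, mu = as.vector(mu_mat))
         else rpois(n, as.vector(mu_mat))
    matrix(x, nrow = nrow(mu_mat))
  }

  blocks <- list(); meta <- list(); labels <- list()
  for (ci in seq_len(design$n_clusters)) {
    cl <- cl_ids[ci]
    n_cell <- design$cluster_sizes[ci]
    mk_cl <- if (is.null(markers)) NULL else
      markers[vapply(markers$clusters, function(s) cl %in% s, logical(1)), ,
              drop = FALSE]
    cy_cl <- if (is.null(cyclers)) NULL else
      cyclers[cyclers$cluster == cl, , drop = FALSE]
    for (cond in design$conditions) {
      # gene x timepoint mean TP10K profile for this cluster/condition
      W <- matrix(base_w, nrow = design$n_genes,
                  ncol = length(design$timepoints),
                  dimnames = list(genes, NULL))
      if (!is.null(mk_cl) && nrow(mk_cl))
        W[mk_cl$gene, ] <- mk_cl$baseline * mk_cl$fold_enrichment
      if (!is.null(cy_cl) && nrow(cy_cl))
        for (k in seq_len(nrow(cy_cl)))
          W[cy_cl$gene[k], ] <- cycler_mean_at(cy_cl[k, ],
                                               design$timepoints, cond)
      for (rep_i in seq_len(design$n_replicates)) {
        for (ti in seq_along(design$timepoints)) {
          wv <- W[, ti]
          Wc <- matrix(wv, nrow = design$n_genes, ncol = n_cell)
          # expressing-fraction dropout for markers of this cluster
          if (!is.null(mk_cl) && nrow(mk_cl))
            for (k in seq_len(nrow(mk_cl)))
              if (mk_cl$expressing_fraction[k] < 1) {
                off <- runif(n_cell) > mk_cl$expressing_fraction[k]
                Wc[match(mk_cl$gene[k], genes), off] <- mk_cl$baseline[k]
              }
          libs <- mean_lib * rlnorm(n_cell, -sdl^2 / 2, sdl)
          mu <- sweep(Wc, 2, libs / colSums(Wc), `*`)
          cnt <- draw_counts(mu)
          id <- sprintf("%s_%s_R%d_T%02d_c%03d", cl, cond, rep_i,
                        design$timepoints[ti], seq_len(n_cell))
          blocks[[length(blocks) + 1L]] <-
            Matrix::Matrix(cnt, sparse = TRUE,
                           dimnames = list(genes, id))
          meta[[length(meta) + 1L]] <-
            data.frame(cell = id, timepoint_h = design$timepoints[ti],
                       condition = cond, replicate = rep_i,
                       batch = paste0(cond, "_R", rep_i), role = "cell",
                       stringsAsFactors = FALSE)
          labels[[length(labels) + 1L]] <- setNames(rep(cl, n_cell), id)
        }
      }
    }
  }

  # planted QC violators: cells engineered to fail specific filter criteria
  bad_ids <- character(0)
  if (!is.null(bad_cells) && sum(bad_cells) > 0) {
    types <- rep(names(bad_cells), bad_cells)
    if ("high_genes" %in% types && design$n_genes <= 6000)
      stop("high_genes violators require n_genes > 6000")
    for (i in seq_along(types)) {
      ty <- types[i]
      wv <- base_w
      lib <- mean_lib
      switch(ty,
        low_genes   = { keep <- sample(design$n_genes, 300)
                        wv[-keep] <- 0; lib <- 15000 },
        low_umi     = { lib <- 2500 },
        high_umi    = { lib <- 150000 },
        low_entropy = { top <- sample(design$n_genes, 3)
                        wv <- wv * 0.1; wv[top] <- sum(wv) * 3 },
        high_genes  = { wv[] <- 1; lib <- 70000 },
        stop("unknown bad-cell type: ", ty))
      mu <- wv / sum(wv) * lib
      cnt <- draw_counts(matrix(mu, ncol = 1))
      id <- sprintf("bad_%s_%02d", ty, i)
      tp <- design$timepoints[1 + (i %% length(design$timepoints))]
      blocks[[length(blocks) + 1L]] <-
        Matrix::Matrix(cnt, sparse = TRUE, dimnames = list(genes, id))
      meta[[length(meta) + 1L]] <-
        data.frame(cell = id, timepoint_h = tp,
                   condition = design$conditions[1], replicate = 1L,
                   batch = paste0(design$conditions[1], "_R1"), role = "cell",
                   stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- setNames(cl_ids[1], id)
      bad_ids <- c(bad_ids, id)
    }
  }

  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  cell_labels <- unlist(labels)

  truth <- list(cell_labels = cell_labels,
                cyclers = cyclers, markers = markers,
                identities = identities,
                bad_cells = bad_ids, empty_wells = character(0))
  list(counts = counts, meta = meta,
       clusters = data.frame(cell = names(cell_labels),
                             cluster = unname(cell_labels),
                             stringsAsFactors = FALSE),
       truth = truth, design = design)
}

#' Classify every gene of a simulation against the ground truth
#'
#' @param truth the `truth` component of [simulate_scdata()] output.
#' @param genes gene universe (rownames of the count matrix).
#' @param cluster cluster id.
#' @return character vector over `genes`: `"cycler"`, `"marker"` or
#'   `"background"` for that cluster (a gene that is both is `"cycler"`).
#' @export
gene_truth_class <- function(truth, genes, cluster) {
  cls <- setNames(rep("background", length(genes)), genes)
  mk <- truth$markers
  if (!is.null(mk)) {
    in_cl <- vapply(mk$clusters, function(s) cluster %in% s, logical(1))
    cls[mk$gene[in_cl]] <- "marker"
  }
  cy <- truth$cyclers
  if (!is.null(cy)) cls[cy$gene[cy$cluster == cluster]] <- "cycler"
  cls
}

#' Append empty-well negative controls
#'
#' Emulates the empty wells carried on each plate as negative controls: `n`
#' pseudo-cells whose only signal is ambient leakage, Poisson counts with
#' per-gene mean `leak_rate` on a small random gene subset.
#'
#' @param counts genes x cells count matrix.
#' @param meta per-cell metadata (as from [simulate_scdata()]).
#' @param n number of empty wells to append.
#' @param leak_rate per-gene Poisson mean of ambient leakage.
#' @param n_leak_genes size of the random gene subset receiving leakage.
#' @param seed integer seed.
#' @return list `counts`, `meta` with the empty wells appended and flagged
#'   `role = "empty"`.
#' @export
add_empty_wells <- function(counts, meta, n, leak_rate,
                            n_leak_genes = 10, seed = 1L) {
  stopifnot(n >= 0, leak_rate >= 0)
  if (n == 0) return(list(counts = counts, meta = meta))
  set.seed(seed)
  G <- nrow(counts)
  cols <- lapply(seq_len(n), function(i) {
    v <- numeric(G)
    idx <- sample(G, min(n_leak_genes, G))
    v[idx] <- rpois(length(idx), leak_rate)
    v
  })
  empty <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  dimnames(empty) <- list(rownames(counts), sprintf("empty_%02d", seq_len(n)))
  meta_e <- data.frame(cell = colnames(empty),
                       timepoint_h = meta$timepoint_h[1],
                       condition = meta$condition[1], replicate = 1L,
                       batch = meta$batch[1], role = "empty",
                       stringsAsFactors = FALSE)
  list(counts = cbind(counts, empty), meta = rbind(meta, meta_e))
}

#' Seventeen-cluster synthetic clock-neuron panel
#'
#' Builds the full synthetic study: 17 clusters of unequal size carrying the
#' marker combinations of the Drosophila clock-neuron classes (s-LNv, l-LNv,
#' LN_ITP, LNd_Trissin, LNd_NPF, LNd, DN1a, DN2, LPN, six DN1p clusters two of
#' which are CNMa-positive, and two marker-poor DN3 clusters), core clock
#' genes cycling with an evening peak (`tim` at ZT14, antiphase in DD in the
#' DN2 cluster only), and one unique planted marker per cluster.
#'
#' @param seed integer seed.
#' @param n_genes total genes (background drawn lognormal).
#' @param size_scale multiplies all cluster sizes (use `< 1` for quick tests).
#' @param bad_cells,empty_wells counts of planted QC violators / empty wells.
#' @return as [simulate_scdata()]; `truth$identities` maps the 17 clusters to
#'   their anatomical labels.
#' @export
sim_clock_panel <- function(seed = 1L, n_genes = 5000, size_scale = 1,
                            bad_cells = 0, empty_wells = 0) {
  identities <- c(cl01 = "s-LNv", cl02 = "l-LNv", cl03 = "LN_ITP",
                  cl04 = "LNd_Trissin", cl05 = "LNd_NPF", cl06 = "LNd",
                  cl07 = "DN1a", cl08 = "DN2", cl09 = "LPN",
                  cl10 = "DN1p_CNMa", cl11 = "DN1p_CNMa",
                  cl12 = "DN1p", cl13 = "DN1p", cl14 = "DN1p", cl15 = "DN1p",
                  cl16 = "DN3", cl17 = "DN3")
  sizes <- pmax(1L, as.integer(round(size_scale *
            c(25, 2, 4, 3, 5, 6, 3, 4, 1, 20, 8, 10, 8, 6, 5, 4, 2))))
  design <- sim_design(n_clusters = 17, cluster_sizes = sizes,
                       n_genes = n_genes, seed = seed)

  mk <- function(...) do.call(rbind, list(...))
  markers <- mk(
    planted_marker("Pdf",      c("cl01", "cl02"), 300),
    planted_marker("sNPF",     c("cl01", "cl04"), 120),
    planted_marker("ITP",      "cl03",            150),
    planted_marker("Trissin",  "cl04",            150),
    planted_marker("AstC-R2",  c("cl05", "cl06"),  60),
    planted_marker("NPF",      "cl05",             80),
    planted_marker("CCHa1",    "cl07",            120),
    planted_marker("AstA",     "cl09",            100),
    planted_marker("AstC",     "cl09",             80, baseline = 0.15),
    planted_marker("gl",       c("cl10", "cl12", "cl13", "cl14", "cl15"), 40),
    planted_marker("Dh31",     c("cl10", "cl11"),  60),
    planted_marker("CNMa",     c("cl10", "cl11"), 100),
    planted_marker("Rh7",      c("cl07", "cl08", "cl14"), 30),
    planted_marker("VGlut",    c("cl10", "cl11", "cl12", "cl13", "cl14",
                                 "cl15", "cl16"), 20, baseline = 0.3),
    do.call(rbind, lapply(1:17, function(i)
      planted_marker(sprintf("mkr%02d", i), sprintf("cl%02d", i), 80,
                     expressing_fraction = if (i == 5) 0.6 else 0.9)))
  )

  clock_cl <- sprintf("cl%02d", 1:16)   # cl17 is a tim-poor DN3
  cyclers <- do.call(rbind, c(
    lapply(clock_cl, function(cl)
      planted_cycler("tim", cl,
                     if (cl == "cl08") "antiphase_in_DD" else "both",
                     fold_amplitude = 3, peak_phase = 14, baseline = 30)),
    lapply(clock_cl, function(cl)
      planted_cycler("vri", cl, "both", 2.5, 16, 15)),
    lapply(clock_cl[1:8], function(cl)
      planted_cycler("Clk", cl, "both", 2, 2, 5)),
    lapply(clock_cl[1:10], function(cl)
      planted_cycler("Pdp1", cl, "both", 2.5, 18, 20))
  ))

  sim <- simulate_scdata(design, cyclers = cyclers, markers = markers,
                         identities = identities,
                         bad_cells = if (bad_cells > 0)
                           c(low_genes = ceiling(bad_cells / 2),
                             low_umi = floor(bad_cells / 2)) else NULL)
  if (empty_wells > 0) {
    ew <- add_empty_wells(sim$counts, sim$meta, empty_wells, leak_rate = 2,
                          seed = seed + 1L)
    sim$counts <- ew$counts; sim$meta <- ew$meta
    sim$truth$empty_wells <- setdiff(ew$meta$cell, sim$clusters$cell)
  }
  sim
}
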