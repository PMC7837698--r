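# Shared fixtures, built once per test run and cached.  All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the 17-cluster clock-neuron panel with QC-passed TP10K matrix
get_panel <- function() cached("panel", function() {
  sim <- sim_clock_panel(seed = 101)
  qc <- filter_cells(sim$counts)
  expr <- to_tp10k(qc$counts)
  meta <- sim$meta[sim$meta$cell %in% colnames(expr), , drop = FALSE]
  cl <- sim$clusters[sim$clusters$cell %in% colnames(expr), , drop = FALSE]
  list(sim = sim, qc = qc, expr = expr, meta = meta, cl = cl)
})

get_panel_markers <- function() cached("panel_markers", function() {
  pd <- get_panel()
  find_markers(pd$expr, pd$cl)
})

# one-cluster LD fixture with 50 cells/timepoint: 30 strong planted cyclers
# (fold 2-4, peak >= 5 TP10K), 10 low-peak cyclers (peak ~0.5 TP10K),
# background noise genes
get_power_fixture <- function() cached("power", function() {
  phases <- rep(c(2, 6, 10, 14, 18, 22, 0, 4, 8, 12, 16, 20),
                length.out = 30)
  cyc <- do.call(rbind, c(
    lapply(1:30, function(i)
      planted_cycler(sprintf("cyc%02d", i), "cl01", "both",
                     fold_amplitude = 2 + (i %% 3),
                     peak_phase = phases[i], baseline = 5 + 2 * i)),
    lapply(1:10, function(i)
      planted_cycler(sprintf("dim%02d", i), "cl01", "both",
                     fold_amplitude = 3, peak_phase = phases[i],
                     baseline = 0.33))))
  des <- sim_design(n_clusters = 1, cluster_sizes = 25, conditions = "LD",
                    n_replicates = 2, n_genes = 1000, baseline_mean = 20,
                    seed = 11)
  sim <- simulate_scdata(des, cyclers = cyc)
  expr <- to_tp10k(sim$counts)
  rec <- suppressWarnings(
    call_cyclers(expr, sim$meta, sim$clusters,
                 rhythm_params(n_permutations = 2000, split_seed = 11)))
  list(sim = sim, expr = expr, rec = rec, cyclers = cyc)
})

# permutation-null p-values: 500 flat genes, 20 cells/timepoint, NB noise
get_null_pvalues <- function() cached("null_p", function() {
  des <- sim_design(n_clusters = 1, cluster_sizes = 20, conditions = "LD",
                    n_replicates = 1, n_genes = 500, baseline_mean = 40,
                    seed = 12)
  sim <- simulate_scdata(des)
  e <- to_tp10k(sim$counts)
  hrs <- sim$meta$timepoint_h
  pp <- rhythm_params(n_permutations = 1000)
  vapply(seq_len(nrow(e)), function(g)
    jtk_test(as.numeric(e[g, ]), hrs, pp, seed = 1000 + g)$p, numeric(1))
})

# annotation inputs derived from the panel
get_annotation <- function() cached("annotation", function() {
  pd <- get_panel()
  rule_genes <- unique(unlist(lapply(default_clock_rules(), function(r)
    c(r$present, r$absent, r$present_any))))
  dot <- dot_stats(pd$expr, pd$cl, rule_genes)
  ldc <- pd$meta$cell[pd$meta$condition == "LD"]
  dot_ld <- dot_stats(pd$expr[, colnames(pd$expr) %in% ldc, drop = FALSE],
                      pd$cl[pd$cl$cell %in% ldc, , drop = FALSE], rule_genes)
  prof <- cluster_profiles(pd$expr, pd$meta, pd$cl)
  calls <- suppressWarnings(annotate_clusters(dot, prof, dot_ld = dot_ld))
  list(dot = dot, dot_ld = dot_ld, prof = prof, calls = calls)
})

# brute-force O(n^2) pair-enumeration Kendall tau-b oracle
oracle_tau_b <- function(x, y) {
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  num <- sum(sx[ut] * sy[ut])
  n <- length(x); n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2)); n2 <- sum(choose(table(y), 2))
  num / sqrt((n0 - n1) * (n0 - n2))
}

# brute-force DFT power at frequency k (no fft), for the F24 oracle
oracle_power <- function(s, k) {
  n <- length(s); idx <- seq_len(n) - 1
  re <- sum(s * cos(2 * pi * k * idx / n))
  im <- sum(s * sin(2 * pi * k * idx / n))
  re^2 + im^2
}
oracle_f24 <- function(s) {
  v <- sum((s - mean(s))^2)
  if (v < 1e-12) return(0)
  P <- vapply(1:3, function(k) oracle_power(s, k), numeric(1))
  w <- c(2, 2, 1)
  w[1] * P[1] / sum(w * P)
}

# small end-to-end pipeline configuration and two cached runs
small_config <- function(seed = 7L) {
  pipeline_config(
    simulate = list(n_genes = 5000, size_scale = 0.25),
    rhythm = rhythm_params(n_permutations = 1000, split_seed = seed),
    rhythm_genes = c("tim", "vri", "Clk", "Pdp1"),
    seed = seed)
}

get_pipeline_runs <- function() cached("pipeline_runs", function() {
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  m1 <- suppressWarnings(run_pipeline(small_config(), d1))
  m2 <- suppressWarnings(run_pipeline(small_config(), d2))
  list(m1 = m1, m2 = m2, d1 = d1, d2 = d2)
})

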