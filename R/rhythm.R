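#' Rhythmicity-detection parameters
#'
#' Gates and settings for 24-h cycler detection.  A transcript is called
#' cycling in a cluster x condition stratum when its BH-corrected permutation
#' JTK q-value is below `q_max`, its F24 spectral score exceeds `f24_min`,
#' its amplitude (peak/trough of the timepoint-mean profile) is at least
#' `amp_min` (a zero trough passes the amplitude gate when the expression
#' requirement is met), and its peak expression is at least `peak_min_tp10k`.
#'
#' @param period_h rhythm period in hours (fixed 24 for a 6 x 4 h design).
#' @param test_phases reference peak phases scanned by the JTK test (hours).
#' @param q_max BH q-value cutoff (strict `<`, default 0.05).
#' @param f24_min F24 cutoff (strict `>`, default 0.5).
#' @param amp_min fold-amplitude cutoff (default 1.5).
#' @param peak_min_tp10k peak-expression floor on the TP10K scale (default 0.8).
#' @param n_permutations permutations for the JTK null (default 20,000).
#' @param split_seed seed for the pseudo-replicate split and permutation
#'   streams.
#' @param detect_frac detectability floor: genes expressed in fewer than this
#'   fraction of a cluster's cells are excluded from testing and from the BH
#'   family (default 0.05).
#' @param f24_method `"averaged"` scores the two pseudo-replicate series
#'   separately and averages; `"concatenated"` scores them as one 12-point
#'   two-cycle series.
#' @return object of class `rhythm_params`.
#' @export
rhythm_params <- function(period_h = 24, test_phases = seq(0, 20, by = 4),
                          q_max = 0.05, f24_min = 0.5, amp_min = 1.5,
                          peak_min_tp10k = 0.8, n_permutations = 20000,
                          split_seed = 1L, detect_frac = 0.05,
                          f24_method = c("averaged", "concatenated")) {
  stopifnot(q_max > 0, q_max < 1, f24_min >= 0, f24_min <= 1, amp_min >= 1,
            peak_min_tp10k >= 0, n_permutations >= 1000)
  structure(list(period_h = period_h, test_phases = test_phases,
                 q_max = q_max, f24_min = f24_min, amp_min = amp_min,
                 peak_min_tp10k = peak_min_tp10k,
                 n_permutations = as.integer(n_permutations),
                 split_seed = as.integer(split_seed),
                 detect_frac = detect_frac,
                 f24_method = match.arg(f24_method)),
            class = "rhythm_params")
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Computed from the joint contingency table of the two vectors by
#' two-dimensional cumulative counting, with the tau-b tie correction in the
#' denominator.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return tau-b in `[-1, 1]`, or `NA` with a warning when either vector is
#'   constant.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("zero variance; tau undefined")
    return(NA_real_)
  }
  m <- as.matrix(table(factor(x, levels = sort(unique(x))),
                       factor(y, levels = sort(unique(y)))))
  cum2 <- function(a) t(apply(apply(a, 2, cumsum), 1, cumsum))
  B <- cum2(m)                      # counts with i' <= i and j' <= j
  tot <- n
  Rcum <- cumsum(rowSums(m))
  Ccum <- cumsum(colSums(m))
  R <- nrow(m); C <- ncol(m)
  G <- tot - outer(Rcum, rep(1, C)) - outer(rep(1, R), Ccum) + B
  H <- matrix(0, R, C)              # counts with i' > i and j' < j
  if (C > 1)
    H[, 2:C] <- outer(rep(1, R), Ccum[1:(C - 1)]) - B[, 1:(C - 1), drop = FALSE]
  nc <- sum(m * G)
  nd <- sum(m * H)
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(rowSums(m), 2))
  n2 <- sum(choose(colSums(m), 2))
  (nc - nd) / sqrt((n0 - n1) * (n0 - n2))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, capped at 1.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

# reference construction shared by jtk_test and call_cyclers: for each phase,
# cosine reference values per timepoint group, pairwise sign matrix and the
# reference tie count entering the tau-b denominator
jtk_references <- function(ut, ng, phases, period = 24) {
  T <- length(ut)
  sgn <- matrix(0, nrow = length(phases), ncol = T * T)
  n2 <- numeric(length(phases))
  for (p in seq_along(phases)) {
    r <- round(cos(2 * pi * (ut - phases[p]) / period), 9)
    s <- sign(outer(r, r, function(a, b) b - a))
    sgn[p, ] <- as.vector(t(s))       # index [a*T + b] in 0-based C layout
    n2[p] <- sum(choose(tapply(ng, r, sum), 2))
  }
  list(sgn = sgn, n2 = n2)
}

#' Permutation JTK test for one gene
#'
#' Treats each cell as a replicate of its timepoint.  For each candidate peak
#' phase, the tie-corrected Kendall correlation between per-cell expression
#' and the cosine reference `cos(2*pi*(t - phase)/24)` is computed; the test
#' statistic is the maximum over phases, which absorbs the phase scan without
#' a multiplicity factor.  The p-value is the permutation tail probability
#' `(count >= T_obs + 1)/(B + 1)` under random reassignment of timepoint
#' labels to cells, exact in expectation under any tie structure.
#'
#' @param values per-cell expression of one gene.
#' @param hours per-cell timepoint in hours.
#' @param params a [rhythm_params()].
#' @param seed integer seed for the permutation stream (default
#'   `params$split_seed`).
#' @return list: `p`, `best_phase_h` (argmax phase, ties to the smallest
#'   offset; `NA` for a constant gene, which gets `p = 1`), and `tau`, the
#'   observed per-phase correlations.
#' @export
jtk_test <- function(values, hours, params = rhythm_params(), seed = NULL) {
  stopifnot(length(values) == length(hours), length(values) >= 3)
  ut <- sort(unique(hours))
  if (length(ut) < 2) stop("need >= 2 distinct timepoints")
  phases <- params$test_phases
  gi <- match(hours, ut)
  ng <- tabulate(gi, nbins = length(ut))
  refs <- jtk_references(ut, ng, phases, params$period_h)
  n <- length(values)
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(values), 2))
  if (n0 - n1 <= 0)
    return(list(p = 1.0, best_phase_h = NA_real_,
                tau = rep(NA_real_, length(phases))))
  denom <- sqrt(pmax(n0 - n1, 0) * pmax(n0 - refs$n2, 0))
  ux <- sort(unique(values))
  code <- match(values, ux) - 1L
  set.seed(seed %||% params$split_seed)
  res <- jtk_perm_engine(code, length(ux), gi - 1L, length(ut),
                         refs$sgn, denom, params$n_permutations)
  list(p = (res$count_ge + 1) / (params$n_permutations + 1),
       best_phase_h = phases[which.max(res$obs_tau)],
       tau = res$obs_tau)
}

#' Random pseudo-replicate split
#'
#' Splits the cells at each timepoint into two random halves (sizes differing
#' by at most one; a single-cell timepoint contributes its value to both
#' halves, with a warning) and returns the two mean time series used for
#' Fourier scoring.
#'
#' @param x expression values: a vector (one gene) or a genes x cells matrix.
#' @param hours per-cell timepoint in hours.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list `a`, `b`: mean series over the sorted timepoints (vectors or
#'   genes x timepoints matrices), with the cell partition in attribute
#'   `"split"`.
#' @export
split_pseudoreplicates <- function(x, hours, seed = 1L) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  stopifnot(ncol(X) == length(hours))
  ut <- sort(unique(hours))
  set.seed(seed)
  split_idx <- lapply(ut, function(t) {
    idx <- which(hours == t)
    if (length(idx) < 2) {
      warning("timepoint ", t, " has < 2 cells; both halves reuse it")
      return(list(a = idx, b = idx))
    }
    pm <- sample(idx)
    k <- ceiling(length(idx) / 2)
    list(a = pm[seq_len(k)], b = pm[-seq_len(k)])
  })
  mean_of <- function(which_half) {
    out <- vapply(split_idx, function(s)
      rowMeans(X[, s[[which_half]], drop = FALSE]), numeric(nrow(X)))
    if (nrow(X) == 1) matrix(out, nrow = 1) else out
  }
  a <- mean_of("a"); b <- mean_of("b")
  if (vec) { a <- drop(a); b <- drop(b) }
  out <- list(a = a, b = b)
  attr(out, "split") <- split_idx
  attr(out, "timepoints") <- ut
  out
}

# per-series fraction of non-DC spectral power at one cycle per series
# length; conjugate bins are folded (Parseval weighting), so the score is the
# fraction of the series' variance carried by the 24-h component
f24_series <- function(s, cycle_bin = 1) {
  n <- length(s)
  v <- sum((s - mean(s))^2)
  if (v <= 1e-12 * max(1, mean(s)^2)) return(0)
  half <- floor(n / 2)
  P <- Mod(fft(s)[2:(half + 1)])^2
  w <- rep(2, half)
  if (n %% 2 == 0) w[half] <- 1          # Nyquist bin has no conjugate
  (w[cycle_bin] * P[cycle_bin]) / sum(w * P)
}

#' F24 spectral score
#'
#' Fraction of non-DC discrete-Fourier power at the 24-h frequency, computed
#' on the two pseudo-replicate mean series.  With the default `"averaged"`
#' method each series is scored separately (a pure 24-h cosine scores 1, a
#' constant series scores 0, and iid noise scores 0.4 in expectation, the
#' 24-h component's share of the non-DC degrees of freedom) and the two
#' scores are averaged.  The `"concatenated"` method appends the series into
#' one two-cycle trace and takes the power fraction at its second harmonic.
#'
#' @param series_a,series_b the two mean time series (equal length, equally
#'   spaced over 24 h).
#' @param method see above.
#' @return score in `[0, 1]`.
#' @export
f24_score <- function(series_a, series_b,
                      method = c("averaged", "concatenated")) {
  method <- match.arg(method)
  stopifnot(length(series_a) == length(series_b), length(series_a) >= 4)
  if (method == "averaged")
    mean(c(f24_series(series_a), f24_series(series_b)))
  else
    f24_series(c(series_a, series_b), cycle_bin = 2)
}

#' Cycling amplitude and peak expression
#'
#' Amplitude is the maximum over minimum of the timepoint-mean profile.  A
#' zero minimum gives an infinite (sentinel) amplitude and is flagged; such
#' transcripts pass the amplitude gate if they meet the peak-expression
#' requirement.
#'
#' @param timepoint_means nonnegative timepoint-mean expression values.
#' @return list: `amplitude` (`Inf` when the trough is zero), `peak`,
#'   `trough`, `zero_min`.
#' @export
amplitude_and_peak <- function(timepoint_means) {
  stopifnot(all(timepoint_means >= 0))
  pk <- max(timepoint_means); tr <- min(timepoint_means)
  list(amplitude = if (tr > 0) pk / tr else Inf,
       peak = pk, trough = tr, zero_min = tr == 0)
}

#' Cosinor phase estimate
#'
#' Least-squares fit of `m(t) = a + b*cos(wt) + c*sin(wt)` with `w = 2*pi/24`;
#' the acrophase is `atan2(c, b) * 24/(2*pi) mod 24` and the relative
#' amplitude is `sqrt(b^2 + c^2)/a`.
#'
#' @param timepoint_means mean expression per timepoint (`>= 3` values).
#' @param hours the timepoints.
#' @param period_h period (default 24).
#' @return list: `phase_h`, `relamp` (`NA` when the mesor is not positive),
#'   `mesor`, `amp`.
#' @export
cosinor_phase <- function(timepoint_means, hours, period_h = 24) {
  stopifnot(length(timepoint_means) == length(hours), length(hours) >= 3)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * hours), sin(w * hours))
  cf <- qr.coef(qr(X), timepoint_means)
  a <- cf[1]; b <- cf[2]; cc <- cf[3]
  amp <- sqrt(b^2 + cc^2)
  ph <- (atan2(cc, b) * period_h / (2 * pi)) %% period_h
  if (ph > period_h - 1e-9) ph <- 0           # canonicalize the wrap-around
  list(phase_h = ph,
       relamp = if (a > 0) amp / a else NA_real_,
       mesor = a, amp = amp)
}

#' Call cycling transcripts per cluster and condition
#'
#' For every gene passing the detectability floor in a cluster x condition
#' stratum, runs the permutation JTK test (cells as replicates), the
#' pseudo-replicate-split F24 score, and the amplitude and peak gates on the
#' timepoint-mean TP10K profile; q-values are BH-adjusted within each
#' stratum.  Per-gene permutation streams are seeded from the gene name so
#' results do not depend on gene order.
#'
#' @param expr genes x cells TP10K matrix (QC-passed).
#' @param meta per-cell metadata with `cell`, `timepoint_h`, `condition`.
#' @param clusters named cluster vector (cell -> cluster) or a data.frame
#'   with columns `cell`, `cluster`.
#' @param params a [rhythm_params()].
#' @param genes optional gene subset to test (detectability still applies).
#' @return data.frame, one row per gene x cluster x condition: `jtk_p`,
#'   `jtk_q`, `best_phase_h`, `f24`, `amplitude`, `peak_tp10k`, `trough`,
#'   `zero_min`, `n_cells`, `is_cycler`.  Strata with a timepoint below two
#'   cells are flagged `low_power` (with a warning); a cluster missing a
#'   timepoint entirely is skipped.
#' @export
call_cyclers <- function(expr, meta, clusters, params = rhythm_params(),
                         genes = NULL) {
  labs <- if (is.data.frame(clusters))
    setNames(clusters$cluster, clusters$cell) else clusters
  meta <- meta[match(colnames(expr), meta$cell), , drop = FALSE]
  if (anyNA(meta$cell)) stop("cells missing from metadata")
  out <- list()
  for (cl in sort(unique(labs[colnames(expr)]))) {
    for (cond in sort(unique(meta$condition))) {
      cells <- colnames(expr)[!is.na(labs[colnames(expr)]) &
                              labs[colnames(expr)] == cl &
                              meta$condition == cond]
      if (!length(cells)) next
      hrs <- meta$timepoint_h[match(cells, meta$cell)]
      ut <- sort(unique(hrs))
      if (length(ut) < 2) { warning(cl, "/", cond,
                                    ": fewer than 2 timepoints; skipped")
                            next }
      npt <- table(hrs)
      low_power <- any(npt < 2)
      if (low_power)
        warning(cl, "/", cond, ": timepoint(s) with < 2 cells; low power")
      sub <- expr[, cells, drop = FALSE]
      det <- Matrix::rowMeans(sub > 0) >= params$detect_frac
      if (!is.null(genes)) det <- det & rownames(expr) %in% genes
      if (!any(det)) next
      X <- as.matrix(sub[det, , drop = FALSE])
      gi <- match(hrs, ut)
      ind <- outer(gi, seq_along(ut), `==`) + 0
      tmeans <- X %*% sweep(ind, 2, colSums(ind), `/`)

      amp <- apply(tmeans, 1, max) / apply(tmeans, 1, min)
      trough <- apply(tmeans, 1, min)
      peak <- apply(tmeans, 1, max)
      amp[trough == 0] <- Inf

      split_seed <- (params$split_seed +
                     str_hash31(paste(cl, cond))) %% 2147483647
      halves <- split_pseudoreplicates(X, hrs, seed = split_seed)
      f24 <- vapply(seq_len(nrow(X)), function(g)
        f24_score(halves$a[g, ], halves$b[g, ], method = params$f24_method),
        numeric(1))

      ng <- tabulate(gi, nbins = length(ut))
      refs <- jtk_references(ut, ng, params$test_phases, params$period_h)
      n <- length(cells)
      n0 <- n * (n - 1) / 2
      p <- numeric(nrow(X)); phase <- rep(NA_real_, nrow(X))
      for (g in seq_len(nrow(X))) {
        x <- X[g, ]
        n1 <- sum(choose(table(x), 2))
        if (n0 - n1 <= 0) { p[g] <- 1; next }
        denom <- sqrt(pmax(n0 - n1, 0) * pmax(n0 - refs$n2, 0))
        ux <- sort(unique(x))
        set.seed((params$split_seed +
                  str_hash31(rownames(X)[g])) %% 2147483647)
        res <- jtk_perm_engine(match(x, ux) - 1L, length(ux), gi - 1L,
                               length(ut), refs$sgn, denom,
                               params$n_permutations)
        p[g] <- (res$count_ge + 1) / (params$n_permutations + 1)
        phase[g] <- params$test_phases[which.max(res$obs_tau)]
      }
      q <- bh_adjust(p)
      amp_ok <- ifelse(trough > 0, amp >= params$amp_min, TRUE)
      rec <- data.frame(gene = rownames(X), cluster = cl, condition = cond,
                        n_cells = n, jtk_p = p, jtk_q = q,
                        best_phase_h = phase, f24 = f24, amplitude = amp,
                        peak_tp10k = peak, trough = trough,
                        zero_min = trough == 0,
                        low_power = low_power,
                        is_cycler = q < params$q_max &
                                    f24 > params$f24_min &
                                    amp_ok &
                                    peak >= params$peak_min_tp10k,
                        stringsAsFactors = FALSE)
      out[[paste(cl, cond)]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
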