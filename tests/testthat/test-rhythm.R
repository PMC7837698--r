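test_that("kendall_tau_b matches pair enumeration on tie-rich input", {
  # exhaustive: all pairs of length-4 vectors over {0,1,2}
  vecs4 <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  keep <- apply(vecs4, 1, function(v) length(unique(v)) > 1)
  vecs4 <- vecs4[keep, , drop = FALSE]
  for (i in seq_len(nrow(vecs4)))
    for (j in seq_len(nrow(vecs4)))
      if (abs(kendall_tau_b(vecs4[i, ], vecs4[j, ]) -
              oracle_tau_b(vecs4[i, ], vecs4[j, ])) > 1e-12)
        fail(sprintf("tau mismatch at (%s) vs (%s)",
                     paste(vecs4[i, ], collapse = ","),
                     paste(vecs4[j, ], collapse = ",")))
  succeed()
  # length-5 vectors against a fixed reference battery, plus stats::cor
  vecs5 <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2, 0:2))
  keep <- apply(vecs5, 1, function(v) length(unique(v)) > 1)
  vecs5 <- vecs5[keep, , drop = FALSE]
  refs <- rbind(c(0, 1, 2, 1, 0), c(1, 2, 3, 4, 5), c(2, 2, 1, 0, 0),
                c(0, 0, 1, 1, 2), c(5, 1, 4, 2, 3))
  for (i in seq_len(nrow(vecs5)))
    for (r in seq_len(nrow(refs))) {
      got <- kendall_tau_b(vecs5[i, ], refs[r, ])
      expect_equal(got, oracle_tau_b(vecs5[i, ], refs[r, ]),
                   tolerance = 1e-12)
      expect_equal(got, suppressWarnings(
        cor(vecs5[i, ], refs[r, ], method = "kendall")), tolerance = 1e-9)
    }
  # monotone vectors
  expect_equal(kendall_tau_b(1:4, c(10, 20, 30, 40)), 1.0)
  expect_equal(kendall_tau_b(1:4, 4:1), -1.0)
  expect_warning(r0 <- kendall_tau_b(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r0))
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(bh_adjust(rep(0.5, 4)), rep(0.5, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.3)
  # hand step-up: q_(i) = min_{j>=i} p_(j) * m / j
  m <- length(p)
  hand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[order(order(p))]
  expect_equal(bh_adjust(p), pmin(1, hand))
})

test_that("F24 is exact on cosines and constants and shift/scale invariant", {
  tps <- c(2, 6, 10, 14, 18, 22)
  cosw <- cos(2 * pi * (tps - 14) / 24)
  expect_equal(f24_score(cosw, cosw), 1.0, tolerance = 1e-9)
  expect_equal(f24_score(rep(3, 6), rep(3, 6)), 0.0)
  # a 12 h rhythm has no 24 h power
  cos12 <- cos(2 * pi * tps / 12)
  expect_equal(f24_score(cos12, cos12), 0.0, tolerance = 1e-9)
  # invariance to additive shift and positive scaling
  set.seed(8)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(f24_score(a, b), f24_score(10 + 3 * a, 2 + 0.5 * b),
               tolerance = 1e-9)
  # agreement with the brute-force DFT oracle on random series
  for (i in 1:50) {
    s <- rnorm(6)
    expect_equal(f24_score(s, s), oracle_f24(s), tolerance = 1e-9)
  }
  # the concatenated variant also scores a pure cosine 1 and a constant 0
  expect_equal(f24_score(cosw, cosw, method = "concatenated"), 1.0,
               tolerance = 1e-9)
  expect_equal(f24_score(rep(1, 6), rep(1, 6), method = "concatenated"), 0.0)
})

test_that("pseudo-replicate splits are seeded, balanced and unbiased", {
  set.seed(21)
  hrs <- rep(c(2, 6, 10, 14, 18, 22), each = 10)
  x <- rnorm(60, 50, 5)
  s1 <- split_pseudoreplicates(x, hrs, seed = 5)
  s2 <- split_pseudoreplicates(x, hrs, seed = 5)
  expect_identical(s1, s2)                      # deterministic given seed
  sp <- attr(s1, "split")
  for (g in sp) {
    expect_lte(abs(length(g$a) - length(g$b)), 1)
    expect_length(intersect(g$a, g$b), 0)
  }
  # halves average back to the timepoint means
  tm <- tapply(x, hrs, mean)
  recomb <- (s1$a * vapply(sp, function(g) length(g$a), 1) +
             s1$b * vapply(sp, function(g) length(g$b), 1)) / 10
  expect_equal(unname(recomb), unname(as.numeric(tm)), tolerance = 1e-10)
  # identical cells give identical halves
  s3 <- split_pseudoreplicates(rep(7, 60), hrs, seed = 1)
  expect_equal(s3$a, rep(7, 6))
  expect_equal(s3$b, rep(7, 6))
  # single-cell timepoints are reused in both halves, with a warning each
  w <- capture_warnings(
    s4 <- split_pseudoreplicates(1:6, c(2, 6, 10, 14, 18, 22), seed = 1))
  expect_true(all(grepl("< 2 cells", w)))
  expect_length(w, 6)
  expect_equal(s4$a, s4$b)
})

test_that("amplitude and peak follow the zero-minimum rule", {
  a <- amplitude_and_peak(c(2, 4, 6, 8, 4, 2))
  expect_equal(a$amplitude, 4.0)
  expect_equal(a$peak, 8.0)
  z <- amplitude_and_peak(c(0, 1, 2, 3, 2, 1))
  expect_true(z$zero_min)
  expect_equal(z$peak, 3.0)
  expect_false(is.finite(z$amplitude))          # sentinel
  expect_equal(amplitude_and_peak(rep(5, 6))$amplitude, 1.0)
})

test_that("cosinor recovers exact phases and flags flat series", {
  tps <- c(2, 6, 10, 14, 18, 22)
  for (ph in c(0, 3.5, 14, 23)) {
    fit <- cosinor_phase(5 + 2 * cos(2 * pi * (tps - ph) / 24), tps)
    expect_equal(fit$phase_h, ph, tolerance = 1e-6)
    expect_equal(fit$relamp, 0.4, tolerance = 1e-9)
  }
  flat <- cosinor_phase(rep(3, 6), tps)
  expect_equal(flat$relamp, 0, tolerance = 1e-12)
})

test_that("jtk_test is exact on noise-free signals and calibrated nulls", {
  tp <- rep(c(2, 6, 10, 14, 18, 22), each = 10)
  pp <- rhythm_params(n_permutations = 1000)
  # perfect cosine: minimum attainable p, phase at the nearest grid offsets
  r <- jtk_test(cos(2 * pi * (tp - 14) / 24), tp, pp, seed = 7)
  expect_equal(r$p, 1 / 1001)
  expect_true(r$best_phase_h %in% c(12, 16))
  # on-grid peak recovers its own phase
  r16 <- jtk_test(cos(2 * pi * (tp - 16) / 24), tp, pp, seed = 7)
  expect_equal(r16$best_phase_h, 16)
  # constant gene: p = 1, phase undefined
  rc <- jtk_test(rep(2, 60), tp, pp, seed = 7)
  expect_equal(rc$p, 1.0)
  expect_true(is.na(rc$best_phase_h))
  # determinism
  set.seed(33); x <- rnorm(60)
  expect_identical(jtk_test(x, tp, pp, seed = 3),
                   jtk_test(x, tp, pp, seed = 3))
})

test_that("jtk p-values are super-uniform under the permutation null", {
  pv <- get_null_pvalues()
  for (alpha in c(0.01, 0.05, 0.1, 0.2)) {
    se <- sqrt(alpha * (1 - alpha) / length(pv))
    expect_lte(mean(pv < alpha), alpha + 3 * se)
  }
  # and not wildly conservative at the working threshold
  expect_gte(mean(pv < 0.05), 0.05 - 3 * sqrt(0.05 * 0.95 / length(pv)))
})

test_that("phase calls are equivariant under timepoint shifts", {
  set.seed(13)
  tp <- rep(c(2, 6, 10, 14, 18, 22), each = 8)
  x <- 5 + 2 * cos(2 * pi * (tp - 10) / 24) + rnorm(48, 0, 0.5)
  pp <- rhythm_params(n_permutations = 1000)
  r0 <- jtk_test(x, tp, pp, seed = 9)
  r4 <- jtk_test(x, tp + 4, pp, seed = 9)
  expect_equal(r4$best_phase_h, (r0$best_phase_h + 4) %% 24)
  expect_equal(r4$p, r0$p)
  tm <- tapply(x, tp, mean)
  tps <- sort(unique(tp))
  c0 <- cosinor_phase(as.numeric(tm), tps)
  c4 <- cosinor_phase(as.numeric(tm), tps + 4)
  expect_equal(c4$phase_h, (c0$phase_h + 4) %% 24, tolerance = 1e-9)
})

test_that("planted cyclers pass the gates and weak/flat genes never do", {
  fx <- get_power_fixture()
  rec <- fx$rec
  strong <- rec[grepl("^cyc", rec$gene), ]
  expect_equal(nrow(strong), 30)
  expect_gte(mean(strong$is_cycler), 0.9)
  # low-peak cyclers fail the 0.8 TP10K expression gate
  dim <- rec[grepl("^dim", rec$gene), ]
  expect_equal(sum(dim$is_cycler), 0)
  # null background genes are called at no more than the chance rate
  bg <- rec[grepl("^g\\d", rec$gene), ]
  expect_lte(mean(bg$is_cycler),
             0.05 + 3 * sqrt(0.05 * 0.95 / nrow(bg)))
  # gate forcing: no call below any gate
  expect_true(all(rec$jtk_q[rec$is_cycler] < 0.05))
  expect_true(all(rec$f24[rec$is_cycler] > 0.5))
  expect_true(all(rec$peak_tp10k[rec$is_cycler] >= 0.8))
  expect_true(all(rec$amplitude[rec$is_cycler] >= 1.5))
})

test_that("raising any gate threshold never enlarges the cycler set", {
  fx <- get_power_fixture()
  rec <- fx$rec
  base <- rhythm_params()
  called <- function(q_max = base$q_max, f24_min = base$f24_min,
                     amp_min = base$amp_min, peak_min = base$peak_min_tp10k) {
    amp_ok <- ifelse(rec$trough > 0, rec$amplitude >= amp_min, TRUE)
    rec$gene[rec$jtk_q < q_max & rec$f24 > f24_min & amp_ok &
             rec$peak_tp10k >= peak_min]
  }
  full <- called()
  expect_true(all(called(q_max = 0.01) %in% full))
  expect_true(all(called(f24_min = 0.7) %in% full))
  expect_true(all(called(amp_min = 2.5) %in% full))
  expect_true(all(called(peak_min = 5) %in% full))
})
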