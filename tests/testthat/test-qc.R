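test_that("cell entropy has its closed forms and symmetry", {
  # uniform G-gene cell: ln G
  for (G in c(10, 100, 2600))
    expect_equal(cell_entropy(rep(7, G)), log(G), tolerance = 1e-9)
  # point mass: 0
  expect_equal(cell_entropy(c(0, 0, 500, 0)), 0)
  # all-zero cell: defined 0 (fails QC downstream on the UMI floor)
  expect_equal(cell_entropy(numeric(10)), 0)
  # permutation invariance in gene order
  v <- c(5, 0, 3, 9, 1, 0, 22)
  expect_equal(cell_entropy(v), cell_entropy(rev(v)))
  # uniform is maximal among same-support distributions
  expect_lt(cell_entropy(c(100, 1, 1, 1)), cell_entropy(rep(1, 4)))
})

test_that("filter_cells keeps boundary cells and drops planted violators", {
  # hand-built boundary cell: exactly 1000 detected genes, exactly 6000 UMIs
  set.seed(4)
  G <- 1500
  boundary <- integer(G); boundary[1:1000] <- 6L
  good <- as.integer(rpois(G, 20)) + 1L        # ~entropy ln(1500) = 7.3
  m <- Matrix::Matrix(cbind(boundary, good, deparse.level = 0), sparse = TRUE,
                      dimnames = list(sprintf("g%04d", 1:G), c("b", "g")))
  rep1 <- filter_cells(m, qc_thresholds(min_umi = 6000))$report
  expect_equal(rep1$n_genes[1], 1000)
  expect_equal(rep1$n_umi[1], 6000)
  expect_true(rep1$pass[1])                    # boundaries are inclusive
  # entropy boundary: threshold equal to the measured entropy still passes
  ent <- rep1$entropy[1]
  th <- qc_thresholds(min_entropy = ent)
  expect_true(filter_cells(m, th)$report$pass[1])
  expect_false(filter_cells(
    m, qc_thresholds(min_entropy = ent + 1e-9))$report$pass[1])
  # one fewer gene/UMI fails
  low <- integer(G); low[1:999] <- 7L
  m2 <- Matrix::Matrix(cbind(low, good, deparse.level = 0), sparse = TRUE,
                       dimnames = list(rownames(m), c("l", "g")))
  expect_false(filter_cells(m2)$report$pass_genes[1])
})

test_that("exactly the planted good cells survive the seeded QC fixture", {
  d <- sim_design(n_clusters = 3, cluster_sizes = c(5, 5, 5),
                  conditions = "LD", n_replicates = 1, n_genes = 8000,
                  baseline_mean = 2.5, seed = 77)
  sim <- simulate_scdata(d, bad_cells = c(low_genes = 2, low_umi = 2,
                                          high_umi = 2, low_entropy = 2,
                                          high_genes = 2))
  expect_length(sim$truth$bad_cells, 10)
  expect_equal(ncol(sim$counts), 100)
  flt <- filter_cells(sim$counts)
  good <- setdiff(colnames(sim$counts), sim$truth$bad_cells)
  expect_setequal(colnames(flt$counts), good)
  expect_equal(sum(flt$report$pass), 90)
  # filtering is idempotent
  flt2 <- filter_cells(flt$counts)
  expect_identical(colnames(flt2$counts), colnames(flt$counts))
  expect_true(all(flt2$report$pass))
})

test_that("TP10K columns sum to 10^4 and invert back to counts", {
  pd <- get_panel()
  cs <- Matrix::colSums(pd$expr)
  expect_lt(max(abs(cs - 1e4)), 1e-6)
  # 50 UMIs in a 20,000-UMI cell is 25 TP10K
  m <- Matrix::Matrix(matrix(c(50, 19950), ncol = 1), sparse = TRUE,
                      dimnames = list(c("a", "b"), "c1"))
  expect_equal(as.numeric(to_tp10k(m)["a", 1]), 25)
  # rescaling by cell totals recovers raw counts exactly
  tot <- Matrix::colSums(pd$qc$counts)
  back <- pd$expr %*% Matrix::Diagonal(x = tot / 1e4)
  expect_lt(max(abs(back - pd$qc$counts)), 1e-8)
  # zero-total cells are an error naming the cell
  z <- Matrix::Matrix(matrix(c(1, 0), ncol = 2, nrow = 1), sparse = TRUE,
                      dimnames = list("g", c("ok", "empty1")))
  expect_error(to_tp10k(z), "empty1")
})

test_that("pseudobulk means conserve the grand mean and match replicates", {
  pd <- get_panel()
  pb <- pseudobulk(pd$expr, pd$meta, c("condition", "replicate"))
  # weighted group means recover the grand mean
  grand <- rowMeans(as.matrix(pd$expr))
  wmean <- as.numeric(pb$mean %*% pb$n_cells) / sum(pb$n_cells)
  expect_equal(unname(wmean), unname(grand), tolerance = 1e-10)
  # single-cell group equals that cell's profile
  one <- pseudobulk(pd$expr[, 1, drop = FALSE],
                    pd$meta[pd$meta$cell == colnames(pd$expr)[1], ,
                            drop = FALSE], "cell")
  expect_equal(unname(one$mean[, 1]), unname(as.numeric(pd$expr[, 1])))
  # replicate concordance of the synthetic study exceeds 0.95
  expect_gt(profile_correlation(pb$mean[, "LD_1"], pb$mean[, "LD_2"]), 0.95)
  expect_gt(profile_correlation(pb$mean[, "DD_1"], pb$mean[, "DD_2"]), 0.95)
})

test_that("profile correlation ranks marker-sharing clusters together", {
  expect_equal(profile_correlation(c(1, 5, 9), c(1, 5, 9)), 1.0)
  a <- c(1, 2, 3, 4); b <- 10 - 2 * a       # negation about the center
  expect_equal(profile_correlation(a, b, log_transform = FALSE), -1.0)
  expect_warning(r <- profile_correlation(c(2, 2, 2), c(1, 5, 9)),
                 "zero-variance")
  expect_true(is.na(r))
  # clusters sharing most markers correlate higher than disjoint ones
  pd <- get_panel()
  labs <- setNames(pd$cl$cluster, pd$cl$cell)[colnames(pd$expr)]
  prof <- function(cl) rowMeans(as.matrix(pd$expr[, labs == cl, drop = FALSE]))
  r_close <- profile_correlation(prof("cl10"), prof("cl11"))  # share 4 markers
  r_far <- profile_correlation(prof("cl10"), prof("cl01"))    # share none
  expect_gt(r_close, r_far)
})
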