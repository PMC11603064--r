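line_embedding <- function(n) {
  emb <- cbind(seq_len(n) / n, 0)
  rownames(emb) <- sprintf("c%03d", seq_len(n))
  emb
}

test_that("pseudotime on a line is the normalized position", {
  emb <- line_embedding(50)
  tr <- assign_pseudotime(emb, root = "c001", k = 3)
  expect_equal(unname(tr$pseudotime["c001"]), 0)
  expect_equal(unname(tr$pseudotime), (0:49) / 49, tolerance = 1e-12)
})

test_that("unreachable cells get NA with a warning", {
  ## three mutually-nearest far cells form their own k = 2 component
  emb <- rbind(line_embedding(30), far1 = c(1000, 1000),
               far2 = c(1000.1, 1000), far3 = c(1000, 1000.1))
  expect_warning(tr <- assign_pseudotime(emb, root = "c001", k = 2),
                 "unreachable")
  expect_true(all(is.na(tr$pseudotime[c("far1", "far2", "far3")])))
  expect_false(anyNA(tr$pseudotime[1:30]))
})

test_that("pseudotime recovers the planted ordering", {
  sim <- small_sim()
  emb <- as.matrix(sim$cells[, c("emb1", "emb2")])
  rownames(emb) <- sim$cells$cell
  tr <- assign_pseudotime(emb, root = sim$cells$cell[which.min(sim$cells$emb1)])
  rho <- cor(tr$pseudotime, sim$truth$cells$true_pseudotime,
             method = "spearman", use = "complete.obs")
  expect_gte(rho, 0.9)
})

test_that("Moran's I: expected value, gradient, and calibration", {
  emb <- line_embedding(100)
  tr <- assign_pseudotime(emb, root = "c001", k = 2)
  ## smooth gradient along the path graph: I close to +1
  grad <- matrix(seq_len(100) / 100, dimnames = list(rownames(emb), "grad"))
  res <- morans_i_test(grad, tr)
  expect_equal(res$expected_i, -1 / 99)
  expect_gt(res$moran_i, 0.9)
  expect_lt(res$q, 0.05)
  ## constant gene: missing statistic, not dynamic
  const <- matrix(1, 100, 1, dimnames = list(rownames(emb), "const"))
  resc <- morans_i_test(const, tr)
  expect_true(is.na(resc$moran_i))
  expect_false(resc$dynamic)
  ## permuted expression: no autocorrelation detected
  set.seed(41)
  perm <- matrix(rnorm(100 * 50), 100, 50,
                 dimnames = list(rownames(emb), sprintf("g%02d", 1:50)))
  resp <- morans_i_test(perm, tr)
  expect_lte(mean(resp$dynamic), 0.07)
})

test_that("Moran's I matches a brute-force path-graph computation", {
  n <- 40
  emb <- line_embedding(n)
  tr <- assign_pseudotime(emb, root = "c001", k = 2)
  set.seed(42)
  x <- rnorm(n)
  res <- morans_i_test(matrix(x, dimnames = list(rownames(emb), "g")), tr)
  W <- as.matrix(tr$weights)
  z <- x - mean(x)
  I_brute <- (n / sum(W)) * sum(outer(z, z) * W) / sum(z^2)
  expect_equal(res$moran_i, I_brute, tolerance = 1e-12)
})

test_that("KS shift tests: trivial cases and planted lag", {
  set.seed(43)
  cells <- data.frame(cell = 1:200, cluster = "x",
                      dose = rep(c(2, 0), each = 100))
  same <- c(runif(100), runif(100))
  ## identical distributions: no signal
  r0 <- ks_shift_test(same, cells, pairs = list(c(2, 0)))
  expect_gt(r0$p, 0.05)
  ## disjoint supports: D = 1
  pt <- c(rep(c(0.1, 0.2, 0.3), length.out = 100),
          rep(c(0.4, 0.5, 0.6), length.out = 100))
  r1 <- suppressWarnings(ks_shift_test(pt, cells, pairs = list(c(2, 0))))
  expect_equal(r1$D, 1)
  ## shifted uniform, 500/arm: D ~ 0.2 detected
  cells2 <- data.frame(cell = 1:1000, cluster = "x",
                       dose = rep(c(2, 0), each = 500))
  pt2 <- c(runif(500), pmax(runif(500) - 0.2, 0))
  r2 <- ks_shift_test(pt2, cells2, pairs = list(c(2, 0)))
  expect_lt(abs(r2$D - 0.2), 0.08)
  expect_lt(r2$q, 0.05)
  expect_lt(r2$median_shift, 0)
  ## undersized arms are skipped with a warning
  cells3 <- data.frame(cell = 1:25, cluster = "x",
                       dose = rep(c(2, 0), c(20, 5)))
  expect_warning(r3 <- ks_shift_test(runif(25), cells3, pairs = list(c(2, 0))),
                 "skipped")
  expect_equal(nrow(r3), 0)
})

test_that("density difference curve arithmetic and bounds", {
  ## mutant entirely in bin 1 of 2, WT uniform -> (+1, -1)
  pt <- c(runif(100), runif(100, 0, 0.5))
  dose <- rep(c(2, 0), each = 100)
  pt[1:100] <- seq(0.0025, 0.9975, length.out = 100)   # exactly uniform WT
  r <- pseudotime_density_diff(pt, dose, bins = 2)
  expect_equal(r$rel_diff, c(1, -1))
  ## identical distributions -> all zeros
  r0 <- pseudotime_density_diff(rep(pt[1:100], 2), dose, bins = 5)
  expect_true(all(r0$rel_diff == 0))
  ## lower bound -1 always
  set.seed(44)
  r2 <- pseudotime_density_diff(runif(300), sample(c(2, 1, 0), 300, TRUE), bins = 10)
  expect_true(all(r2$rel_diff >= -1, na.rm = TRUE))
  expect_error(pseudotime_density_diff(runif(10), rep(0, 10)), "reference")
})
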