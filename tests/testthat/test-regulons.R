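test_that("AUCell extremes: sets inside and outside the window", {
  ## 100 genes, window = 5; counts decreasing so gene g001 ranks first
  m <- matrix(rep(100:1, each = 2), 2, 100, byrow = FALSE)
  m <- t(matrix(100:1, 100, 2))
  counts <- toy_counts(m, genes = sprintf("g%03d", 1:100))
  regs <- list(top = sprintf("g%03d", 1:5), bottom = sprintf("g%03d", 90:100))
  a <- aucell_scores(counts, regs, top_frac = 0.05, seed = 1)
  expect_equal(unname(a[, "top"]), c(1, 1))
  expect_equal(unname(a[, "bottom"]), c(0, 0))
  expect_true("top" %in% attr(a, "small_regulons") == FALSE)
})

test_that("AUCell matches a brute-force recovery-curve oracle", {
  set.seed(71)
  counts <- toy_counts(matrix(sample(1:500, 200), 1, 200),
                       genes = sprintf("g%03d", 1:200))
  reg <- list(r = sample(colnames(counts), 50))
  a <- aucell_scores(counts, reg, top_frac = 0.05, seed = 1)
  ## oracle: explicit recovery-curve integration on the same (tie-free) ranks
  x <- as.numeric(counts[1, ])
  rk <- rank(-x)
  w <- ceiling(0.05 * 200)
  hits <- sort(rk[match(reg$r, colnames(counts))])
  curve <- vapply(seq_len(w), function(r) sum(hits <= r), numeric(1))
  max_curve <- vapply(seq_len(w), function(r) min(r, min(50, w)), numeric(1))
  expect_equal(unname(a[1, 1]), sum(curve) / sum(max_curve), tolerance = 1e-12)
})

test_that("AUC is invariant to monotone transforms of counts", {
  set.seed(72)
  counts <- toy_counts(matrix(sample(1:300, 300), 2, 150),
                       genes = sprintf("g%03d", 1:150))
  reg <- list(r = sample(colnames(counts), 20))
  a1 <- aucell_scores(counts, reg, seed = 5)
  counts2 <- counts; counts2@x <- counts2@x^2
  a2 <- aucell_scores(counts2, reg, seed = 5)
  expect_equal(a1, a2)
})

test_that("RSS extremes and brute-force JSD oracle", {
  clusters <- rep(c("A", "B"), each = 10)
  act <- cbind(ind_A = as.numeric(clusters == "A"),
               out_A = as.numeric(clusters == "B"),
               unif = rep(1, 20))
  rss <- regulon_specificity(act, clusters)
  expect_equal(rss["ind_A", "A"], 1)
  expect_equal(rss["out_A", "A"], 0)       # disjoint supports, log2
  ## uniform activity vs half-population indicator: direct JSD arithmetic
  P <- rep(1 / 20, 20); Q <- as.numeric(clusters == "A") / 10
  M <- (P + Q) / 2
  kl2 <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  jsd <- 0.5 * kl2(P, M) + 0.5 * kl2(Q, M)
  expect_equal(rss["unif", "A"], 1 - jsd, tolerance = 1e-12)
  ## bounds on random activities
  set.seed(73)
  ar <- matrix(runif(20 * 6), 20, 6, dimnames = list(NULL, paste0("r", 1:6)))
  rs <- regulon_specificity(ar, clusters)
  expect_true(all(rs >= 0 & rs <= 1))
  ## relabeling cells permutes nothing material
  perm <- sample(20)
  expect_equal(regulon_specificity(ar[perm, ], clusters[perm]), rs)
})

test_that("planted regulons peak in their active segment", {
  sim <- small_sim()
  regs <- lapply(sim$truth$regulons, as.character)
  a <- aucell_scores(sim$counts, regs, seed = 1)
  rss <- regulon_specificity(a, sim$cells$cluster)
  hits <- vapply(names(regs), function(tf) {
    seg <- attr(sim$truth$regulons[[tf]], "active_segment")
    colnames(rss)[which.max(rss[tf, ])] == seg
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("differential regulons: null and planted behaviour", {
  set.seed(74)
  cells <- data.frame(cell = 1:120, cluster = rep("A", 120),
                      dose = rep(c(2, 0), each = 60))
  act <- cbind(null = runif(120), hit = c(runif(60, 0.4, 0.6), runif(60, 0.1, 0.3)))
  out <- differential_regulons(act, cells)
  expect_false(out$flagged[out$regulon == "null"])
  expect_true(out$flagged[out$regulon == "hit"])
  expect_lt(out$delta_auc[out$regulon == "hit"], 0)
  ## identical constant distributions: p ~ 1, unflagged
  act2 <- cbind(flat = rep(0.5, 120))
  out2 <- differential_regulons(act2, cells)
  expect_false(out2$flagged)
})
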