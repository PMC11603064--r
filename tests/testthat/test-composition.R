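test_that("proportion table: arithmetic, retention of zero clusters, order", {
  cells <- data.frame(cell = sprintf("c%d", 1:14),
                      sample = rep(c("s1", "s2"), c(10, 4)),
                      cluster = c(rep("A", 4), rep("B", 6), rep("B", 4)))
  p <- proportions_table(cells)
  expect_equal(p["s1", "A"], 0.4)
  expect_equal(p["s2", "A"], 0)                      # zero retained as 0
  expect_equal(unname(rowSums(p)), c(1, 1))
  set.seed(1)
  p2 <- proportions_table(cells[sample(nrow(cells)), ])
  expect_equal(p2[rownames(p), colnames(p)], p, ignore_attr = TRUE)
})

test_that("moderated test handles degenerate and 2-group inputs", {
  props <- matrix(rep(c(0.3, 0.7), each = 6), 6, 2,
                  dimnames = list(paste0("s", 1:6), c("A", "B")))
  out <- moderated_prop_test(props, rep(c("wt", "ko"), each = 3))
  expect_equal(out$statistic, c(0, 0))               # identical proportions
  expect_equal(out$p, c(1, 1))
  expect_error(moderated_prop_test(props, c("a", "a", "a", "a", "a", "b")),
               "fewer than 2")
})

test_that("with prior df 0 the moderated t equals the ordinary t", {
  set.seed(31)
  props <- matrix(runif(8 * 3, 0.1, 0.5), 8, 3,
                  dimnames = list(paste0("s", 1:8), c("A", "B", "C")))
  props <- props / rowSums(props)
  groups <- rep(c("wt", "ko"), each = 4)
  out <- moderated_prop_test(props, groups, prior_df = 0)
  for (cl in colnames(props)) {
    y <- asin(sqrt(props[, cl]))
    tt <- t.test(y[groups == "ko"] * 1, y[groups == "wt"], var.equal = TRUE)
    ## sign depends on factor level order; compare magnitudes and p
    expect_equal(abs(out$statistic[out$cluster == cl]),
                 unname(abs(tt$statistic)), tolerance = 1e-9)
    expect_equal(out$p[out$cluster == cl], tt$p.value, tolerance = 1e-9)
  }
})

test_that("moderated variances sit between gene-wise and prior", {
  set.seed(32)
  props <- matrix(runif(10 * 5, 0.05, 0.4), 10, 5)
  props <- props / rowSums(props)
  colnames(props) <- LETTERS[1:5]; rownames(props) <- paste0("s", 1:10)
  groups <- rep(c("wt", "ko"), each = 5)
  out <- moderated_prop_test(props, groups)
  y <- asin(sqrt(props))
  s2 <- sapply(seq_len(ncol(y)), function(j) {
    r <- y[, j] - ave(y[, j], groups)
    sum(r^2) / (10 - 2)
  })
  ## var.post is a convex combination of s2 and a common prior value:
  ## it tracks s2 monotonically and strictly compresses its spread
  if (stats::sd(out$var_post) > 1e-12)     # full shrinkage -> constant post
    expect_gt(cor(out$var_post, s2, method = "spearman"), 0.99)
  expect_lt(diff(range(out$var_post)), diff(range(s2)))
  ## every var.post moves from s2 toward one common crossing point
  delta <- out$var_post - s2
  if (any(delta < 0) && any(delta > 0))
    expect_lt(max(s2[delta > 0]), min(s2[delta < 0]) + 1e-12)
})

test_that("a planted depletion attains the smallest q", {
  set.seed(33)
  base <- c(A = 0.3, B = 0.25, C = 0.2, D = 0.15, E = 0.1)
  draw <- function(p) as.vector(rmultinom(1, 2000, p))
  dep <- base; dep["C"] <- dep["C"] * 0.7; dep <- dep / sum(dep)
  tab <- rbind(t(replicate(4, draw(base))), t(replicate(4, draw(dep))))
  colnames(tab) <- names(base); rownames(tab) <- paste0("s", 1:8)
  props <- tab / rowSums(tab)
  out <- moderated_prop_test(props, rep(c("wt", "het"), each = 4))
  expect_identical(out$cluster[which.min(out$q)], "C")
})

test_that("composition tests are calibrated on null multinomial worlds", {
  ## many independent 5-cluster null tables: fraction p < 0.05 near nominal
  set.seed(34)
  base <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  ps <- replicate(40, {
    tab <- t(replicate(8, as.vector(rmultinom(1, 1500, base))))
    props <- tab / rowSums(tab)
    colnames(props) <- LETTERS[1:5]; rownames(props) <- paste0("s", 1:8)
    moderated_prop_test(props, rep(c("wt", "ko"), each = 4))$p
  })
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.02); expect_lte(frac, 0.08)
})
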