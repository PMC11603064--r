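test_that("hypergeometric ORA: exact fixture and set handling", {
  universe <- letters[1:20]
  out <- hypergeom_ora(letters[1:5], universe, list(S = letters[1:5]))
  expect_equal(out$p, 1 / choose(20, 5), tolerance = 1e-12)
  ## enumeration oracle for the same tail
  p_enum <- sum(vapply(5:5, function(k)
    choose(5, k) * choose(15, 5 - k) / choose(20, 5), numeric(1)))
  expect_equal(out$p, p_enum, tolerance = 1e-12)
  ## zero overlap with min_overlap 1 -> omitted
  out2 <- hypergeom_ora(letters[1:5], universe,
                        list(S = letters[1:5], Z = letters[6:10]))
  expect_identical(out2$set, "S")
  ## overlap at expectation -> one-sided p >= 0.5
  uni <- sprintf("u%03d", 1:100)
  out3 <- hypergeom_ora(uni[1:10], uni, list(S = c(uni[1], uni[11:19])))
  expect_gte(out3$p, 0.5)                      # k = 1 = E[k]
  expect_error(hypergeom_ora(c("a", "zzz"), universe, list(S = "a")),
               "outside the universe")
})

test_that("ORA p-values are monotone decreasing in the overlap", {
  uni <- sprintf("u%03d", 1:60)
  ps <- vapply(1:8, function(k) {
    hypergeom_ora(uni[1:10], uni,
                  list(S = c(uni[1:k], uni[31:(40 - k)])))$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("resampling enrichment: self-consistency and saturation", {
  pool_genes <- sprintf("g%04d", 1:1000)
  target <- pool_genes[seq(1, 1000, by = 5)]        # 20% of everything
  set.seed(61)
  ## query = one random draw from the pool: fold ~ 1, p moderate
  folds <- ps <- numeric(10)
  for (i in 1:10) {
    q <- sample(pool_genes[1:500], 100)
    r <- resample_enrichment(q, pool_genes, target, draw_size = 100,
                             B = 200, seed = i)
    folds[i] <- r$fold; ps[i] <- r$p
  }
  expect_lt(abs(mean(folds) - 1), 0.25)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  ## target covering the pool: saturated overlap, p = 1
  r2 <- resample_enrichment(pool_genes[1:50], pool_genes, pool_genes,
                            draw_size = 50, B = 50, seed = 1)
  expect_equal(r2$p, 1)
  expect_equal(r2$median_null, 50)
  ## draw larger than pool is rejected
  expect_error(resample_enrichment("g0001", pool_genes, target,
                                   draw_size = 900, top_frac = 0.5), "pool")
})

test_that("resampling p-values are roughly uniform under the null", {
  pool_genes <- sprintf("g%04d", 1:400)
  target <- pool_genes[1:80]
  set.seed(62)
  ps <- vapply(1:60, function(i) {
    q <- sample(pool_genes[1:200], 50)
    resample_enrichment(q, pool_genes, target, draw_size = 50,
                        B = 199, seed = 1000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Yates chi-square formula, clamping and symmetry", {
  expect_equal(chisq_yates(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chisq_yates(matrix(c(10, 10, 10, 10), 2))$p, 1)
  expect_equal(chisq_yates(matrix(c(20, 10, 10, 20), 2))$statistic, 5.4)
  ## |ad-bc| = 10 < N/2 = 20.5 -> clamped to 0
  expect_equal(chisq_yates(matrix(c(11, 10, 10, 10), 2))$statistic, 0)
  ## invariance under transposition and simultaneous row/col swap
  m <- matrix(c(25, 7, 12, 30), 2)
  expect_equal(chisq_yates(t(m))$statistic, chisq_yates(m)$statistic)
  expect_equal(chisq_yates(m[2:1, 2:1])$statistic, chisq_yates(m)$statistic)
  ## zero margin
  expect_equal(chisq_yates(matrix(c(0, 5, 0, 7), 2))$p, 1)
})

test_that("Fisher exact agrees with enumeration on small tables", {
  ## [[1,0],[0,1]]: two tables share these margins, one-sided-greater p = 0.5
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p, 0.5)
  ## brute-force hypergeometric enumeration oracle for N <= 20
  enum_p <- function(m) {
    k <- m[1, 1]; K <- sum(m[1, ]); n <- sum(m[, 1]); N <- sum(m)
    ks <- max(0, n - (N - K)):min(K, n)
    sum(vapply(ks[ks >= k], function(kk)
      choose(K, kk) * choose(N - K, n - kk) / choose(N, n), numeric(1)))
  }
  set.seed(63)
  for (i in 1:20) {
    m <- matrix(rpois(4, 3), 2)
    if (any(c(rowSums(m), colSums(m)) == 0)) next
    expect_equal(fisher_exact(m)$p, enum_p(m), tolerance = 1e-10)
  }
  ## proportional margins: greater-side p near 1... at least >= 0.5
  expect_gte(fisher_exact(matrix(c(20, 20, 20, 20), 2))$p, 0.5)
})
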