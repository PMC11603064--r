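test_that("simulation is deterministic given config and seed", {
  a <- simulate_dataset(small_config(seed = 7))
  b <- simulate_dataset(small_config(seed = 7))
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$genes, b$truth$genes)
  d <- simulate_dataset(small_config(seed = 8))
  expect_false(identical(as.matrix(a$counts), as.matrix(d$counts)))
})

test_that("config validation rejects inconsistent worlds", {
  expect_error(sim_config(frac_repressed = 0.9, frac_dynamic = 0.5), "sum")
  expect_error(sim_config(samples_per_dose = c(`0` = 0L, `1` = 3L, `2` = 3L)),
               "no samples")
  expect_error(sim_config(n_genes = 50, frac_repressed = 0.001), "rounds to 0")
  expect_error(sim_config(doses = c(0, 3)), "subset")
})

test_that("null effect configs plant nothing", {
  cfg <- small_config(seed = 3, frac_repressed = 0, frac_activated = 0,
                      maturation_lag = 0, n_timing_shifted = 0L)
  cfg$effect_repressed_log2fc_per_lost_allele <- 0
  cfg$effect_activated_log2fc_KO <- 0
  sim <- simulate_dataset(cfg)
  lfc <- as.matrix(sim$truth$genes[, c("lfc_dose0", "lfc_dose1", "lfc_dose2")])
  expect_true(all(lfc == 0))
})

test_that("simulate_null_dataset strips every genotype effect", {
  sim <- small_null()
  expect_false(any(sim$truth$genes$class %in% c("repressed", "activated")))
  expect_true(all(sim$truth$genes$timing_shift == 0))
  lfc <- as.matrix(sim$truth$genes[, c("lfc_dose0", "lfc_dose1", "lfc_dose2")])
  expect_true(all(lfc == 0))
  expect_equal(sim$truth$cells$true_pseudotime, sim$truth$cells$eff_pseudotime)
})

test_that("single-dose config yields a single dose and no genotype shifts", {
  cfg <- small_config(seed = 5)
  cfg$doses <- 2L
  sim <- simulate_dataset(cfg)
  expect_identical(unique(sim$cells$dose), 2L)
  expect_true(all(is.na(sim$truth$genes$lfc_dose0)))
  expect_true(all(sim$truth$genes$lfc_dose2 == 0))
})

test_that("null genes in truth always carry zero log2 fold change", {
  tg <- small_sim()$truth$genes
  nul <- tg[tg$class %in% c("null", "mito"), ]
  expect_true(all(nul$lfc_dose0 == 0 & nul$lfc_dose1 == 0 & nul$lfc_dose2 == 0))
})

test_that("library sizes are matched within multinomial noise", {
  sim <- small_sim()
  rel <- abs(Matrix::rowSums(sim$counts) - sim$truth$cells$libsize) /
    sim$truth$cells$libsize
  expect_lt(mean(rel), 0.05)
})

test_that("mito genes use the reserved prefix and sit near the planted share", {
  sim <- small_sim()
  mito <- grepl("^mt-", colnames(sim$counts))
  expect_identical(sum(mito),
                   sum(sim$truth$genes$class == "mito"))
  share <- sum(sim$counts[, mito]) / sum(sim$counts)
  expect_lt(abs(share - 0.005), 0.002)
})

test_that("planted dose effects are recovered from pseudobulk ratios", {
  ## full stated world: mean KO/WT log2 ratio of repressed genes ~ 2 x effect
  sim <- fixture("recovery_sim", function() simulate_dataset(sim_config(seed = 202)))
  cells <- sim$cells
  cells$cluster <- "all"
  pb <- aggregate_pseudobulk(sim$counts, cells)
  dm <- dose_means(pb)
  tg <- sim$truth$genes
  rep_g <- tg$gene[tg$class == "repressed"]
  act_g <- tg$gene[tg$class == "activated"]
  expect_lt(abs(mean(log2(dm[rep_g, "0"] / dm[rep_g, "2"])) - 1.0), 0.15)
  expect_lt(abs(mean(log2(dm[act_g, "0"] / dm[act_g, "2"])) + 1.0), 0.15)
  ## Het: repressed shift ~ 0.5, activated attenuated to ~ -0.2
  expect_lt(abs(mean(log2(dm[rep_g, "1"] / dm[rep_g, "2"])) - 0.5), 0.15)
  expect_lt(abs(mean(log2(dm[act_g, "1"] / dm[act_g, "2"])) + 0.2), 0.15)
})

test_that("null dataset counts are independent of dose label", {
  sim <- fixture("null_sim", function() simulate_null_dataset(sim_config(seed = 101)))
  ko <- sim$cells$dose == 0
  wt <- sim$cells$dose == 2
  set.seed(1)
  genes <- sample(colnames(sim$counts), 300)
  p <- vapply(genes, function(g) {
    suppressWarnings(wilcox.test(sim$counts[ko, g], sim$counts[wt, g],
                                 exact = FALSE)$p.value)
  }, numeric(1))
  expect_gt(mean(p < 0.05, na.rm = TRUE), 0.01)
  expect_lt(mean(p < 0.05, na.rm = TRUE), 0.09)
})

test_that("planted regulon targets peak near their TF", {
  sim <- small_sim()
  tg <- sim$truth$genes
  for (tf in names(sim$truth$regulons)) {
    tf_peak <- tg$peak_time[tg$gene == tf]
    tgt_peaks <- tg$peak_time[match(sim$truth$regulons[[tf]], tg$gene)]
    expect_true(all(abs(tgt_peaks - tf_peak) < 0.1))
  }
})
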