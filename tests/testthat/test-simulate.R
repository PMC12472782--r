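test_that("generated matrix has the configured shape and positive values", {
  cfg <- sim_config(n_proteins = 30, n_per_cell = 3, sexes = FALSE,
                    seed = 1)
  sim <- simulate_dataset(cfg)
  expect_equal(dim(sim$matrix), c(30, 12))
  cfg2 <- sim_config(n_proteins = 30, n_per_cell = 3, sexes = TRUE,
                     seed = 1)
  expect_equal(ncol(simulate_dataset(cfg2)$matrix), 24)
  expect_true(all(sim$matrix > 0))
  expect_equal(sim$annotation$sample_id, colnames(sim$matrix))
  expect_equal(table(paste(sim$annotation$genotype,
                           sim$annotation$treatment))[["TG VEH"]], 3)
})

test_that("no-effect configuration yields all true ratios of 1", {
  sim <- simulate_dataset(sim_config(n_proteins = 10, n_per_cell = 3,
                                     spike_fraction = 0, cv = 0.2,
                                     depth_sigma = 0, outlier_rate = 0,
                                     sexes = FALSE, seed = 1))
  expect_true(all(sim$truth$proteins$true_ratio == 1))
  expect_false(any(sim$truth$proteins$is_spiked))
})

test_that("spiked proteins carry the configured two-sided effect", {
  sim <- simulate_dataset(sim_config(n_proteins = 100, n_per_cell = 3,
                                     effect_fraction = 0.35,
                                     spike_fraction = 0.1, outlier_rate = 0,
                                     sexes = FALSE, seed = 2))
  tr <- sim$truth$proteins
  expect_equal(sum(tr$is_spiked), 10)
  expect_setequal(unique(tr$true_ratio[tr$is_spiked]), c(1.35, 0.65))
  expect_true(all(tr$true_ratio[!tr$is_spiked] == 1))
})

test_that("same config and seed reproduce the dataset bit-identically", {
  cfg <- sim_config(n_proteins = 40, n_per_cell = 3, seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
})

test_that("noise-free, depth-free data equal the exact cell-mean pattern", {
  sim <- simulate_dataset(sim_config(n_proteins = 20, n_per_cell = 3,
                                     cv = 0, depth_sigma = 0,
                                     outlier_rate = 0, spike_fraction = 0.2,
                                     sexes = FALSE, seed = 3))
  ann <- sim$annotation
  tr <- sim$truth$proteins
  case <- ann$genotype == "TG" & ann$treatment == "VEH"
  base <- sim$matrix[, which(!case)[1]]
  for (j in seq_len(ncol(sim$matrix))) {
    expected <- if (case[j]) base * tr$true_ratio else base
    expect_equal(unname(sim$matrix[, j]), unname(expected))
  }
})

test_that("empirical noise level and spike ratio match the configuration", {
  sim <- simulate_dataset(sim_config(n_proteins = 2000, n_per_cell = 6,
                                     cv = 0.2, depth_sigma = 0,
                                     outlier_rate = 0, spike_fraction = 0.5,
                                     sexes = FALSE, seed = 4))
  ann <- sim$annotation
  wt_veh <- ann$genotype == "WT" & ann$treatment == "VEH"
  cvs <- apply(sim$matrix[, wt_veh], 1, function(v) sd(v) / mean(v))
  expect_gt(median(cvs), 0.18)
  expect_lt(median(cvs), 0.22)
  # spiked-cell mean ratio within 2% of the configured ratio
  tr <- sim$truth$proteins
  case <- ann$genotype == "TG" & ann$treatment == "VEH"
  ctrl <- ann$genotype == "WT" & ann$treatment == "VEH"
  ratio <- rowMeans(sim$matrix[, case]) / rowMeans(sim$matrix[, ctrl])
  up <- tr$is_spiked & tr$true_ratio > 1
  dn <- tr$is_spiked & tr$true_ratio < 1
  expect_lt(abs(mean(ratio[up]) - 1.35), 0.02 * 1.35)
  expect_lt(abs(mean(ratio[dn]) - 0.65), 0.02 * 0.65)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cv = 1), "cv")
  expect_error(sim_config(n_proteins = 0), ">= 1")
  expect_error(sim_config(outlier_rate = 0.2), "outlier_rate")
  expect_error(sim_config(outlier_rate = 0.01, outlier_factor = 0.5),
               "outlier_factor")
})

test_that("outlier injection modifies exactly the reported cells", {
  m <- toy_matrix(matrix(runif(100, 1, 2), 10, 10))
  inj <- inject_outliers(m, rate = 0.05, factor = 10, seed = 11)
  expect_equal(nrow(inj$cells), 5)
  for (i in seq_len(nrow(inj$cells))) {
    p <- inj$cells$protein_id[i]
    s <- inj$cells$sample_id[i]
    expect_equal(inj$matrix[p, s], 10 * m[p, s])
  }
  untouched <- !(outer(rownames(m), colnames(m), paste) %in%
                   cell_key(inj$cells))
  expect_identical(inj$matrix[untouched], m[untouched])
  # rate 0: unchanged; same seed: same cells
  expect_identical(inject_outliers(m, 0, 10, 1)$matrix, m)
  expect_identical(inject_outliers(m, 0.05, 10, 11)$cells, inj$cells)
})
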