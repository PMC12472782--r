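test_that("fold change and log2 transform follow the mean-ratio formula", {
  fc <- fold_change(rep(1.25, 3), rep(1, 3))
  expect_equal(fc[["fc"]], 1.25)
  expect_equal(round(fc[["log2fc"]], 2), 0.32)
  expect_equal(fold_change(c(2, 2), c(2, 2))[["log2fc"]], 0)
  # swapping groups negates log2fc
  a <- c(1.1, 1.4, 1.2); b <- c(0.8, 0.9, 1.0)
  expect_equal(fold_change(a, b)[["log2fc"]],
               -fold_change(b, a)[["log2fc"]])
  expect_true(is.na(fold_change(c(NA, NA), c(1, 2))[["fc"]]))
})

test_that("normality routing picks Student's t for normal-looking groups", {
  set.seed(42)
  a <- rnorm(10, 5, 1); b <- rnorm(10, 6, 1)
  res <- route_and_test(a, b)
  expect_equal(res$test_used, "student_t")
  expect_equal(res$p_value, t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("nonparametric route gives the exact enumeration p for small n", {
  # constant group fails Shapiro-Wilk routing -> Mann-Whitney
  res <- route_and_test(c(1, 2, 3), c(4, 4, 4))
  expect_equal(res$test_used, "mann_whitney")
  # clearly non-normal data: exact two-sided p for complete separation
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  skewed <- route_and_test(c(a, 100), c(b, 1000))  # forces nonparametric
  expect_equal(skewed$test_used, "mann_whitney")
  expect_equal(skewed$p_value,
               mw_enumeration_p(c(a, 100), c(b, 1000)))
})

test_that("degenerate and undersized groups are handled per the contract", {
  res <- route_and_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  expect_equal(route_and_test(c(1, 2), c(1, 2, 3))$test_used, "untested")
})

test_that("exact Mann-Whitney equals label enumeration on random cases", {
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- runif(n1); b <- runif(n2) + runif(1, -0.5, 0.5)
    p_pkg <- suppressWarnings(
      wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(p_pkg, mw_enumeration_p(a, b), tolerance = 1e-12)
  }
})

test_that("volcano classification applies the joint rule with strict cuts", {
  expect_equal(classify_volcano(0.40, 0.01, 0.32), "up")
  expect_equal(classify_volcano(0.40, 0.2, 0.32), "ns")     # fails p
  expect_equal(classify_volcano(log2(0.75), 0.01, 0.25), "down")
  expect_equal(classify_volcano(0.32, 0.01, 0.25), "ns")    # boundary strict
  expect_equal(classify_volcano(0.40, 0.05, 0.32), "ns")    # p boundary
  expect_equal(classify_volcano(0.40, 0.01, 0.10), "ns")    # fails min change
  expect_equal(classify_volcano(NA, 0.01, NA), "ns")
})

test_that("exchanging case and control swaps up and down calls", {
  sim <- simulate_dataset(sim_config(n_proteins = 150, n_per_cell = 6,
                                     spike_fraction = 0.2, outlier_rate = 0,
                                     depth_sigma = 0, sexes = FALSE,
                                     seed = 8))
  ann <- sim$annotation
  # symmetric cuts so the label swap is an exact mirror
  tab <- differential_table(sim$matrix, ann, contrast = "genotype",
                            up_cut = 0.32, down_cut = -0.32,
                            min_change = 0)
  flip <- ann
  flip$genotype <- ifelse(ann$genotype == "WT", "TG", "WT")
  tab2 <- differential_table(sim$matrix, flip, contrast = "genotype",
                             up_cut = 0.32, down_cut = -0.32,
                             min_change = 0)
  expect_equal(tab$p_value, tab2$p_value, tolerance = 1e-12)
  expect_equal(tab$volcano_class == "up", tab2$volcano_class == "down")
  expect_equal(tab$log2fc, -tab2$log2fc, tolerance = 1e-12)
})

test_that("the differential table carries consistent derived columns", {
  sim <- simulate_dataset(sim_config(n_proteins = 60, n_per_cell = 4,
                                     spike_fraction = 0.2, sexes = FALSE,
                                     outlier_rate = 0, seed = 9))
  tab <- differential_table(sim$matrix, sim$annotation)
  expect_equal(tab$fc, tab$mean_case / tab$mean_control)
  expect_equal(tab$log2fc, log2(tab$fc))
  expect_equal(tab$neg_log10_p, -log10(tab$p_value))
  expect_equal(tab$pct_change, abs(tab$fc - 1))
  expect_true(all(tab$test_used %in%
                    c("student_t", "mann_whitney", "untested")))
})
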