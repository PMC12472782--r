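.as_cell_means <- function(cell_means) {
  m <- matrix(as.numeric(cell_means), 2, 2, byrow = !is.matrix(cell_means))
  if (is.matrix(cell_means)) m <- cell_means
  if (any(!is.finite(m))) stop("cell means must be finite")
  dimnames(m) <- list(genotype = c("WT", "TG"), treatment = c("VEH", "DCI"))
  m
}

#' Two-way effect decomposition of a 2x2 cell-mean pattern
#'
#' Standard additive decomposition: grand mean, genotype and treatment main
#' effects, and interaction effects
#' `int_ij = mu_ij - grand - row_i - col_j` (which sum to zero across each
#' row and column). Also reports Cohen's
#' `f = sqrt(mean(int^2)) / sigma` and the noncentrality contribution per
#' subject, `sum(int^2) / sigma^2`.
#'
#' @param cell_means Length-4 numeric in the order WT-VEH, WT-DCI, TG-VEH,
#'   TG-DCI, or a 2x2 matrix (rows = genotype WT/TG, cols = treatment
#'   VEH/DCI).
#' @param sigma Common within-cell SD, in the same units as the means
#'   (> 0).
#' @return List of class `"effect_decomposition"`: `cell_means`,
#'   `grand_mean`, `main_genotype`, `main_treatment`, `interaction`
#'   (2x2), `cohen_f`, `ncp_per_n`, `sigma`.
#' @export
#' @examples
#' decompose_effects(c(1, 1, 0.65, 1), sigma = 0.2)$cohen_f  # 0.4375
decompose_effects <- function(cell_means, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  m <- .as_cell_means(cell_means)
  grand <- mean(m)
  row_eff <- rowMeans(m) - grand
  col_eff <- colMeans(m) - grand
  int <- m - grand - matrix(row_eff, 2, 2) -
    matrix(col_eff, 2, 2, byrow = TRUE)
  structure(list(
    cell_means = m, grand_mean = grand,
    main_genotype = row_eff, main_treatment = col_eff,
    interaction = int,
    cohen_f = sqrt(mean(int^2)) / sigma,
    ncp_per_n = sum(int^2) / sigma^2,
    sigma = sigma
  ), class = "effect_decomposition")
}

#' Analytic power of the 2x2 interaction F-test
#'
#' Power of the 1-df genotype-by-treatment interaction contrast
#' (difference-in-differences) in a balanced two-way ANOVA with `n_per_cell`
#' subjects per cell: the upper-tail probability of a noncentral
#' `F(1, 4(n - 1), lambda)` beyond the central-F critical value at `alpha`,
#' with `lambda = n * sum(interaction effects^2) / sigma^2`.
#'
#' @param design An [decompose_effects()] object, or a length-4/2x2
#'   cell-mean pattern combined with `sigma`.
#' @param n_per_cell Integer >= 2.
#' @param alpha Test level (default 0.05).
#' @param sigma Within-cell SD (only when `design` is a raw cell-mean
#'   pattern).
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' interaction_power(decompose_effects(c(1, 1, 0.65, 1), 0.2), 11)
interaction_power <- function(design, n_per_cell, alpha = 0.05,
                              sigma = NULL) {
  if (!inherits(design, "effect_decomposition"))
    design <- decompose_effects(design, sigma)
  if (n_per_cell < 2) stop("n_per_cell must be >= 2")
  lambda <- n_per_cell * design$ncp_per_n
  df2 <- 4 * (n_per_cell - 1)
  crit <- qf(1 - alpha, 1, df2)
  pf(crit, 1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest per-cell sample size reaching the target interaction power
#'
#' @inheritParams interaction_power
#' @param target_power Required power (default 0.80).
#' @param max_n Search bound.
#' @return Smallest integer `n >= 2` with
#'   `interaction_power(design, n) >= target_power`.
#' @export
#' @examples
#' solve_n(decompose_effects(c(1, 1, 0.65, 1), 0.2))  # 11
solve_n <- function(design, alpha = 0.05, target_power = 0.8,
                    sigma = NULL, max_n = 100000L) {
  if (!inherits(design, "effect_decomposition"))
    design <- decompose_effects(design, sigma)
  if (design$ncp_per_n <= .Machine$double.eps)
    stop("zero interaction: no finite sample size reaches the target power")
  for (n in 2:max_n) {
    if (interaction_power(design, n, alpha) >= target_power) return(n)
  }
  stop("no n <= max_n reaches the target power")
}

#' A-priori power design for a treatment-normalized genotype effect
#'
#' Convenience wrapper for the planning scenario behind the pipeline's
#' study design: the untreated transgenic cell deviates from the control
#' mean by `effect_fraction` while treatment restores it (the treated
#' wild-type cell is assumed unchanged), with common within-cell SD
#' `cv * control_mean`. Solves the per-cell sample size for the interaction
#' contrast and reports the buffered recommendation.
#'
#' @param control_mean Control-cell mean (units arbitrary; default 1).
#' @param effect_fraction Genotype effect as a fraction of the control mean
#'   (default 0.35).
#' @param cv Within-cell SD as a fraction of the control mean (default
#'   0.20).
#' @param alpha Test level (default 0.05).
#' @param target_power Required power (default 0.80).
#' @param buffer Extra animals per cell added to the solved n to absorb
#'   procedural losses (default 1).
#' @return List of class `"power_design"`: `decomposition`, `alpha`,
#'   `target_power`, `n_per_cell`, `power_at_n`, `n_recommended`,
#'   `n_total`, `cohen_f`, `lambda`.
#' @export
#' @examples
#' power_design()  # n_per_cell 11, n_recommended 12, n_total 48
power_design <- function(control_mean = 1, effect_fraction = 0.35,
                         cv = 0.2, alpha = 0.05, target_power = 0.8,
                         buffer = 1L) {
  means <- c(control_mean, control_mean,
             control_mean * (1 - effect_fraction), control_mean)
  dec <- decompose_effects(means, sigma = cv * control_mean)
  n <- solve_n(dec, alpha = alpha, target_power = target_power)
  structure(list(
    decomposition = dec, alpha = alpha, target_power = target_power,
    n_per_cell = n, power_at_n = interaction_power(dec, n, alpha),
    n_recommended = n + as.integer(buffer),
    n_total = 4L * (n + as.integer(buffer)),
    cohen_f = dec$cohen_f, lambda = n * dec$ncp_per_n
  ), class = "power_design")
}

#' @export
print.power_design <- function(x, ...) {
  cat("2x2 interaction power design\n")
  cat(sprintf("  Cohen's f: %.4f   lambda at solved n: %.3f\n",
              x$cohen_f, x$lambda))
  cat(sprintf("  alpha: %.3f   target power: %.2f\n",
              x$alpha, x$target_power))
  cat(sprintf("  solved n per cell: %d (power %.3f)\n",
              x$n_per_cell, x$power_at_n))
  cat(sprintf("  recommended (buffered): %d per cell, %d total\n",
              x$n_recommended, x$n_total))
  invisible(x)
}

#' Monte-Carlo power of the 2x2 interaction F-test
#'
#' Simulation cross-check of [interaction_power()]: draws normal cell
#' samples and computes the exact balanced-design F statistic of the
#' interaction contrast for each replicate, returning the empirical
#' rejection rate (with its binomial standard error).
#'
#' @inheritParams interaction_power
#' @param n_sim Number of replicates (default 10000).
#' @param seed Integer RNG seed.
#' @return List: `power` (rejection rate), `se` (binomial SE), `n_sim`.
#' @export
interaction_power_mc <- function(design, n_per_cell, alpha = 0.05,
                                 sigma = NULL, n_sim = 10000, seed = 1L) {
  if (!inherits(design, "effect_decomposition"))
    design <- decompose_effects(design, sigma)
  set.seed(seed)
  n <- n_per_cell
  mu <- as.numeric(design$cell_means)
  # per replicate: cell means and variances of n draws per cell
  xbar <- matrix(NA_real_, n_sim, 4)
  ssw <- numeric(n_sim)
  for (cell in 1:4) {
    draws <- matrix(rnorm(n_sim * n, mu[cell], design$sigma), n_sim, n)
    xbar[, cell] <- rowMeans(draws)
    ssw <- ssw + rowSums((draws - rowMeans(draws))^2)
  }
  # 1-df interaction contrast (difference in differences)
  contr <- xbar[, 1] - xbar[, 2] - xbar[, 3] + xbar[, 4]
  ss_int <- n * contr^2 / 4
  df2 <- 4 * (n - 1)
  f_stat <- ss_int / (ssw / df2)
  rej <- mean(f_stat > qf(1 - alpha, 1, df2))
  list(power = rej, se = sqrt(rej * (1 - rej) / n_sim), n_sim = n_sim)
}
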