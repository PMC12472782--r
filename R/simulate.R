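#' Simulation configuration for synthetic spike-in abundance data
#'
#' Builds and validates the parameter set for [simulate_dataset()]. Defaults
#' describe the study conditions the downstream analysis assumes: a balanced
#' 2x2 genotype-by-treatment design split into male/female strata (6 animals
#' per stratum cell, i.e. 12 per genotype-by-treatment cell, 48 samples in
#' total), within-cell noise equal to 20% of the cell mean, a 35% genotype
#' effect carried by 5% of proteins in the untreated transgenic cell only
#' (treatment restores control levels), protein baselines spread log-uniformly
#' over 4-9 decades, log-normal per-sample depth multipliers, and a small
#' rate of gross (10x) outlier cells.
#'
#' @param n_proteins Number of proteins (rows).
#' @param n_per_cell Samples per genotype-by-treatment cell within each sex
#'   stratum (per cell overall when `sexes = FALSE`).
#' @param cv Within-cell coefficient of variation, as a fraction of the cell
#'   mean; must lie in `[0, 1)`.
#' @param effect_fraction Genotype effect size as a fraction of the control
#'   mean (the untreated transgenic cell mean is `baseline * (1 +/- effect)`).
#' @param spike_fraction Fraction of proteins carrying the genotype effect.
#' @param baseline_log10_range Length-2 numeric, `c(lo, hi)` decades for the
#'   log-uniform protein baseline means.
#' @param depth_sigma Log-scale SD of the per-sample depth multipliers
#'   (`0` disables depth variation).
#' @param outlier_rate Fraction of matrix cells multiplied by
#'   `outlier_factor`; must lie in `[0, 0.1)`.
#' @param outlier_factor Multiplier applied to injected outlier cells (> 1).
#' @param sexes Logical; split samples into M/F strata (doubles the sample
#'   count).
#' @param seed Integer seed; fully determines the output.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 50, n_per_cell = 3, seed = 1)
sim_config <- function(n_proteins = 2000, n_per_cell = 6, cv = 0.2,
                       effect_fraction = 0.35, spike_fraction = 0.05,
                       baseline_log10_range = c(4, 9), depth_sigma = 0.2,
                       outlier_rate = 0.005, outlier_factor = 10,
                       sexes = TRUE, seed = 1L) {
  stopifnot(length(n_proteins) == 1, length(n_per_cell) == 1)
  if (n_proteins < 1 || n_per_cell < 1)
    stop("n_proteins and n_per_cell must be >= 1")
  if (!is.numeric(cv) || cv < 0 || cv >= 1)
    stop("cv must lie in [0, 1): multiplicative normal noise with cv >= 1 ",
         "would cross zero too often")
  if (spike_fraction < 0 || spike_fraction > 1)
    stop("spike_fraction must lie in [0, 1]")
  if (effect_fraction < 0 || effect_fraction >= 1)
    stop("effect_fraction must lie in [0, 1)")
  if (length(baseline_log10_range) != 2 ||
      baseline_log10_range[1] > baseline_log10_range[2])
    stop("baseline_log10_range must be an increasing pair")
  if (depth_sigma < 0) stop("depth_sigma must be >= 0")
  if (outlier_rate < 0 || outlier_rate >= 0.1)
    stop("outlier_rate must lie in [0, 0.1)")
  if (outlier_rate > 0 && outlier_factor <= 1)
    stop("outlier_factor must be > 1")
  structure(list(
    n_proteins = as.integer(n_proteins), n_per_cell = as.integer(n_per_cell),
    cv = cv, effect_fraction = effect_fraction,
    spike_fraction = spike_fraction,
    baseline_log10_range = baseline_log10_range, depth_sigma = depth_sigma,
    outlier_rate = outlier_rate, outlier_factor = outlier_factor,
    sexes = isTRUE(sexes), seed = as.integer(seed)
  ), class = "sim_config")
}

# truncated multiplicative noise: eps ~ N(0, cv^2), redrawn while eps <= -1
# so abundances stay strictly positive
.rnoise <- function(n, cv) {
  if (cv == 0) return(rep(0, n))
  eps <- rnorm(n, 0, cv)
  bad <- which(eps <= -1)
  while (length(bad)) {
    eps[bad] <- rnorm(length(bad), 0, cv)
    bad <- bad[eps[bad] <= -1]
  }
  eps
}

#' Generate a synthetic abundance matrix with known spiked truth
#'
#' Draws protein baselines log-uniformly, spikes a fraction of proteins in
#' the untreated transgenic (TG-VEH) cell only -- half up by
#' `1 + effect_fraction`, half down by `1 - effect_fraction`, emulating a
#' genotype effect that the treatment normalizes -- applies multiplicative
#' within-cell noise (truncated so abundances stay positive), a per-sample
#' depth multiplier, and optionally injects gross outlier cells.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `matrix` (numeric proteins x samples matrix),
#'   `annotation` (data.frame: sample_id, genotype, treatment, sex) and
#'   `truth` (list with `proteins`: data.frame of protein_id, is_spiked,
#'   true_ratio; and `outlier_cells`: data.frame of protein_id, sample_id).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 20, n_per_cell = 3,
#'                                    sexes = FALSE, seed = 1))
#' dim(sim$matrix)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sex_levels <- if (config$sexes) c("M", "F") else NA_character_
  ann <- expand.grid(
    rep = seq_len(config$n_per_cell),
    treatment = c("VEH", "DCI"),
    genotype = c("WT", "TG"),
    sex = sex_levels,
    stringsAsFactors = FALSE
  )
  ann$sample_id <- paste0(
    ifelse(is.na(ann$sex), "S", ann$sex), "_",
    ann$genotype, "_", ann$treatment, "_", ann$rep
  )
  ann <- ann[, c("sample_id", "genotype", "treatment", "sex")]
  n_s <- nrow(ann)
  p_ids <- sprintf("P%04d", seq_len(config$n_proteins))

  lo <- config$baseline_log10_range[1]
  hi <- config$baseline_log10_range[2]
  baseline <- 10^runif(config$n_proteins, lo, hi)

  n_spiked <- round(config$spike_fraction * config$n_proteins)
  spiked <- rep(FALSE, config$n_proteins)
  true_ratio <- rep(1, config$n_proteins)
  if (n_spiked > 0) {
    idx <- sample.int(config$n_proteins, n_spiked)
    spiked[idx] <- TRUE
    n_up <- ceiling(n_spiked / 2)
    dir_up <- sample(idx, n_up)
    true_ratio[dir_up] <- 1 + config$effect_fraction
    true_ratio[setdiff(idx, dir_up)] <- 1 - config$effect_fraction
  }

  # cell means: effect confined to the TG-VEH cell
  is_case <- ann$genotype == "TG" & ann$treatment == "VEH"
  means <- outer(baseline, rep(1, n_s))
  means[, is_case] <- baseline * true_ratio

  eps <- matrix(.rnoise(length(means), config$cv), nrow = config$n_proteins)
  depth <- if (config$depth_sigma > 0)
    exp(rnorm(n_s, 0, config$depth_sigma)) else rep(1, n_s)
  mat <- means * (1 + eps) * rep(depth, each = config$n_proteins)
  dimnames(mat) <- list(p_ids, ann$sample_id)

  outlier_cells <- data.frame(protein_id = character(0),
                              sample_id = character(0))
  if (config$outlier_rate > 0) {
    inj <- inject_outliers(mat, config$outlier_rate, config$outlier_factor,
                           seed = config$seed + 1L)
    mat <- inj$matrix
    outlier_cells <- inj$cells
  }

  list(
    matrix = mat,
    annotation = ann,
    truth = list(
      proteins = data.frame(protein_id = p_ids, is_spiked = spiked,
                            true_ratio = true_ratio),
      outlier_cells = outlier_cells
    )
  )
}

#' Inject gross multiplicative outliers into an abundance matrix
#'
#' Multiplies `floor(rate * length(matrix))` randomly chosen cells by
#' `factor`, returning both the modified matrix and the list of affected
#' cells; used as a ground-truth fixture for outlier-removal validation.
#'
#' @param matrix Numeric proteins x samples matrix with dimnames.
#' @param rate Fraction of cells to modify, in `[0, 0.1)`.
#' @param factor Multiplier (> 1) applied to chosen cells.
#' @param seed Integer seed; the same seed always selects the same cells.
#' @return List with `matrix` (modified copy) and `cells` (data.frame:
#'   protein_id, sample_id).
#' @export
inject_outliers <- function(matrix, rate, factor, seed) {
  if (rate < 0 || rate >= 0.1) stop("rate must lie in [0, 0.1)")
  if (rate > 0 && factor <= 1) stop("factor must be > 1")
  n_out <- floor(rate * length(matrix))
  if (n_out == 0)
    return(list(matrix = matrix,
                cells = data.frame(protein_id = character(0),
                                   sample_id = character(0))))
  set.seed(seed)
  idx <- sample.int(length(matrix), n_out)
  matrix[idx] <- matrix[idx] * factor
  rc <- arrayInd(idx, dim(matrix))
  cells <- data.frame(protein_id = rownames(matrix)[rc[, 1]],
                      sample_id = colnames(matrix)[rc[, 2]])
  cells <- cells[order(cells$protein_id, cells$sample_id), ]
  rownames(cells) <- NULL
  list(matrix = matrix, cells = cells)
}
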