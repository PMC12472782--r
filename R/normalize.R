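.sample_totals <- function(matrix) {
  tot <- colSums(matrix, na.rm = TRUE)
  if (any(tot <= 0))
    stop("zero-total sample(s): ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  tot
}

.as_strata <- function(matrix, strata) {
  if (is.null(strata)) strata <- rep("all", ncol(matrix))
  strata <- as.character(strata)
  strata[is.na(strata)] <- "all"
  if (length(strata) != ncol(matrix))
    stop("strata must have one entry per sample")
  factor(strata)
}

#' Down-scaling normalization factors
#'
#' Within each stratum, every sample is scaled to the lowest sample total:
#' `factor_s = min(stratum totals) / total_s`. Factors therefore lie in
#' `(0, 1]` with at least one factor equal to 1 per stratum, and applying
#' them makes every sample total equal its stratum minimum. Missing values
#' are ignored in totals.
#'
#' @param matrix Numeric proteins x samples matrix.
#' @param strata Optional per-sample stratum labels (e.g. sex); `NULL` or
#'   `NA` entries collapse to a single stratum.
#' @return Named numeric vector of per-sample multipliers.
#' @export
#' @examples
#' m <- cbind(S1 = c(40, 60), S2 = c(100, 100), S3 = c(150, 250))
#' down_scaling_factors(m)
down_scaling_factors <- function(matrix, strata = NULL) {
  tot <- .sample_totals(matrix)
  strata <- .as_strata(matrix, strata)
  mins <- tapply(tot, strata, min)
  unname_safe <- as.numeric(mins[as.character(strata)]) / tot
  setNames(unname_safe, colnames(matrix))
}

#' Mean-based normalization factors
#'
#' `factor_s = grand mean of per-sample means / per-sample mean_s`, so all
#' samples end up with equal mean abundance.
#'
#' @inheritParams down_scaling_factors
#' @return Named numeric vector of per-sample multipliers.
#' @export
mean_based_factors <- function(matrix) {
  mu <- colMeans(matrix, na.rm = TRUE)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("zero or undefined sample mean(s)")
  setNames(mean(mu) / mu, colnames(matrix))
}

#' Total-count normalization factors
#'
#' `factor_s = grand mean of sample totals / total_s`, equalizing all sample
#' totals at the grand mean.
#'
#' @inheritParams down_scaling_factors
#' @return Named numeric vector of per-sample multipliers.
#' @export
total_count_factors <- function(matrix) {
  tot <- .sample_totals(matrix)
  setNames(mean(tot) / tot, colnames(matrix))
}

#' Housekeeping-protein normalization factors
#'
#' Scales each sample by the mean abundance of a reference protein set
#' (e.g. beta-actin and beta-tubulin):
#' `factor_s = grand mean of per-sample reference means / reference mean_s`.
#'
#' @inheritParams down_scaling_factors
#' @param reference_ids Character vector of reference protein IDs; all must
#'   be present and non-missing in every sample.
#' @return Named numeric vector of per-sample multipliers.
#' @export
housekeeping_factors <- function(matrix, reference_ids) {
  miss <- setdiff(reference_ids, rownames(matrix))
  if (length(miss))
    stop("reference protein(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  ref <- matrix[reference_ids, , drop = FALSE]
  if (anyNA(ref))
    stop("reference protein(s) have missing values")
  mu <- colMeans(ref)
  if (any(mu <= 0)) stop("zero reference mean(s)")
  setNames(mean(mu) / mu, colnames(matrix))
}

#' Apply per-sample normalization factors
#' @inheritParams down_scaling_factors
#' @param factors Named per-sample multipliers (as returned by the
#'   `*_factors()` functions).
#' @return Normalized matrix.
#' @export
apply_factors <- function(matrix, factors) {
  stopifnot(length(factors) == ncol(matrix))
  if (!is.null(names(factors))) factors <- factors[colnames(matrix)]
  sweep(matrix, 2, factors, "*")
}

#' Normalize an abundance matrix by one of four per-sample schemes
#'
#' The pipeline default is `"down_scaling"` (scale every sample to the
#' lowest total within its sex stratum); the three alternatives are kept for
#' comparison via [evaluate_normalizations()].
#'
#' @inheritParams down_scaling_factors
#' @param annotation Optional sample annotation; supplies sex strata when
#'   `by_sex = TRUE`.
#' @param method One of `"down_scaling"`, `"mean"`, `"total_count"`,
#'   `"housekeeping"`.
#' @param reference_ids Reference proteins (housekeeping method only).
#' @param by_sex Compute stratum factors independently per sex (down-scaling
#'   only; the other schemes are globally defined).
#' @return List of class `"normalization_result"`: `method`, `factors`,
#'   `stratum` (per-sample labels), `normalized` matrix.
#' @export
normalize_abundance <- function(matrix, annotation = NULL,
                                method = c("down_scaling", "mean",
                                           "total_count", "housekeeping"),
                                reference_ids = NULL, by_sex = TRUE) {
  method <- match.arg(method)
  strata <- NULL
  if (by_sex && !is.null(annotation)) {
    annotation <- validate_annotation(annotation, matrix)
    if (!all(is.na(annotation$sex))) strata <- annotation$sex
  }
  factors <- switch(method,
    down_scaling = down_scaling_factors(matrix, strata),
    mean = mean_based_factors(matrix),
    total_count = total_count_factors(matrix),
    housekeeping = housekeeping_factors(matrix, reference_ids)
  )
  structure(list(method = method, factors = factors,
                 stratum = if (is.null(strata))
                   rep("all", ncol(matrix)) else as.character(strata),
                 normalized = apply_factors(matrix, factors)),
            class = "normalization_result")
}

# row-centred log2 profile; NA-safe
.rel_log2 <- function(matrix) {
  lg <- log2(matrix)
  lg - rowMeans(lg, na.rm = TRUE)
}

#' Compare the four normalization schemes on three diagnostics
#'
#' For raw data and each applicable method reports: `cv_totals`, the CV of
#' post-normalization sample totals (depth removal); `median_cell_cv`, the
#' median within-cell CV across proteins (within-group tightness); and
#' `low_quartile_distortion`, the mean absolute change (in log2 units) of
#' the row-centred cross-sample expression profile relative to raw, over the
#' lowest-abundance quartile of proteins (distortion of the signal of weakly
#' expressed proteins). Lower is better for all three.
#'
#' @inheritParams normalize_abundance
#' @return data.frame with one row per method (plus `raw`).
#' @export
evaluate_normalizations <- function(matrix, annotation,
                                    reference_ids = NULL, by_sex = TRUE) {
  annotation <- validate_annotation(annotation, matrix)
  groups <- sample_groups(annotation, by_sex = by_sex)
  low_q <- rowMeans(matrix, na.rm = TRUE) <=
    quantile(rowMeans(matrix, na.rm = TRUE), 0.25)
  raw_rel <- .rel_log2(matrix)

  diag_one <- function(norm) {
    tot <- colSums(norm, na.rm = TRUE)
    cv_tot <- sd(tot) / mean(tot)
    cell_cv <- unlist(lapply(levels(groups), function(g) {
      sub <- norm[, groups == g, drop = FALSE]
      mu <- rowMeans(sub, na.rm = TRUE)
      s <- apply(sub, 1, sd, na.rm = TRUE)
      (s / mu)[mu > 0]
    }))
    dist_low <- mean(abs(.rel_log2(norm) - raw_rel)[low_q, ], na.rm = TRUE)
    c(cv_totals = cv_tot, median_cell_cv = median(cell_cv, na.rm = TRUE),
      low_quartile_distortion = dist_low)
  }

  methods <- c("mean", "down_scaling", "total_count")
  if (!is.null(reference_ids)) methods <- c(methods, "housekeeping")
  rows <- lapply(methods, function(m) {
    nr <- normalize_abundance(matrix, annotation, method = m,
                              reference_ids = reference_ids,
                              by_sex = by_sex)
    diag_one(nr$normalized)
  })
  out <- as.data.frame(do.call(rbind, c(list(diag_one(matrix)), rows)))
  out <- cbind(method = c("raw", methods), out)
  rownames(out) <- NULL
  out
}
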