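#' KNN distance scores for a within-group abundance vector
#'
#' For each value, the score is the mean absolute distance to its `k`
#' nearest other values in the same group. Large scores mark values that sit
#' far from the local bulk of the group; the score is symmetric under any
#' permutation of the input.
#'
#' @param values Numeric vector (one protein's abundances within one group),
#'   no missing values; at least 3 values.
#' @param k Number of neighbours, `1 <= k <= length(values) - 1`.
#' @return Nonnegative numeric score vector aligned with `values`.
#' @export
#' @examples
#' knn_outlier_scores(c(1, 2, 3, 100), k = 2)
knn_outlier_scores <- function(values, k) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (k < 1 || k > n - 1) stop("k must lie in [1, n - 1]")
  d <- abs(outer(values, values, "-"))
  diag(d) <- Inf
  apply(d, 1, function(row) mean(sort(row, partial = k)[seq_len(k)]))
}

# robust z of KNN scores: centre = per-protein median; scale = MAD of the
# median-centred scores pooled across all proteins of the same group (the
# multiplicative noise model puts every protein's log-scale scores on a
# common scale, so pooling gives a stable estimate that 5-6 values per
# protein cannot). IQR fallback when the pooled MAD collapses to zero.
.pooled_scale <- function(residuals) {
  scale <- mad(residuals, center = 0)
  if (scale == 0) scale <- IQR(residuals) / 1.349
  scale
}

#' Remove within-group abundance outliers by KNN robust-z screening
#'
#' For every protein and every experimental group (genotype x treatment,
#' further split by sex when annotated), computes KNN distance scores on
#' log10 abundances -- after removing each sample's median log level within
#' the group, so depth differences neither mask nor mimic cell-level
#' anomalies -- and flags values whose robust z-score -- centred at the
#' protein's median score, scaled by the MAD of median-centred scores pooled
#' over all proteins of the group (IQR fallback) -- exceeds `z_threshold`.
#' Flagged cells are set to
#' missing -- removed, not imputed -- so downstream means and tests use the
#' remaining values. Groups with fewer than 3 non-missing values are skipped
#' with a warning.
#'
#' @param matrix Numeric proteins x samples matrix (positive abundances,
#'   `NA` allowed).
#' @param annotation Sample annotation data.frame (see
#'   [read_sample_annotation()]).
#' @param k Neighbour count; default `min(3, n_group - 1)` per group.
#' @param z_threshold Robust z cutoff. The default (20) is calibrated by
#'   simulation so that under Gaussian multiplicative within-group noise at
#'   group sizes of 5-6 fewer than ~0.1% of clean cells are flagged, while
#'   gross (10x) outliers score far above it; the KNN score's robust z is
#'   strongly right-skewed, so conventional value-based cutoffs such as 3.5
#'   do not transfer to it.
#' @param by_sex Split groups by sex when the annotation carries it.
#' @param max_iter Sweeps are repeated on the cleaned matrix until no new
#'   cell is flagged (removing extreme cells tightens the pooled scale
#'   slightly, which can expose borderline cells), so the returned matrix
#'   is a fixpoint: a further run flags nothing. `max_iter` bounds the
#'   number of sweeps.
#' @return List of class `"outlier_report"` with elements `matrix` (cleaned
#'   copy), `flagged` (data.frame: protein_id, sample_id, value, score),
#'   `k`, `z_threshold`, `iterations`.
#' @export
remove_outliers <- function(matrix, annotation, k = NULL, z_threshold = 20,
                            by_sex = TRUE, max_iter = 10L) {
  annotation <- validate_annotation(annotation, matrix)
  all_flagged <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pass <- .flag_outliers_once(matrix, annotation, k, z_threshold, by_sex,
                                warn = iter == 1L)
    matrix <- pass$matrix
    if (nrow(pass$flagged) > 0) all_flagged[[iter]] <- pass$flagged
    if (nrow(pass$flagged) == 0 || iter >= max_iter) break
  }
  flagged <- do.call(rbind, c(list(.empty_flags()), all_flagged))
  rownames(flagged) <- NULL
  structure(list(matrix = matrix, flagged = flagged,
                 k = if (is.null(k)) NA_integer_ else as.integer(k),
                 z_threshold = z_threshold, iterations = iter),
            class = "outlier_report")
}

.empty_flags <- function() {
  data.frame(protein_id = character(0), sample_id = character(0),
             value = numeric(0), score = numeric(0))
}

.flag_outliers_once <- function(matrix, annotation, k, z_threshold, by_sex,
                                warn = TRUE) {
  groups <- sample_groups(annotation, by_sex = by_sex)
  flagged <- vector("list", nlevels(groups))
  skipped <- character(0)
  for (gi in seq_along(levels(groups))) {
    g <- levels(groups)[gi]
    cols <- which(groups == g)
    sub <- matrix[, cols, drop = FALSE]
    # scores are computed on log10 values with each sample's median log
    # level (within the group) removed, so per-sample depth differences do
    # not masquerade as, or mask, cell-level outliers
    lg <- log10(ifelse(!is.na(sub) & sub > 0, sub, NA))
    if (nrow(lg) >= 10)  # depth offsets need enough proteins to estimate
      lg <- sweep(lg, 2, apply(lg, 2, median, na.rm = TRUE), "-")
    score_rows <- vector("list", nrow(sub))
    idx_rows <- vector("list", nrow(sub))
    for (p in seq_len(nrow(sub))) {
      v <- lg[p, ]
      ok <- which(!is.na(v))
      n <- length(ok)
      if (n < 3) {
        if (n >= 1) skipped <- c(skipped, g)
        next
      }
      kk <- if (is.null(k)) min(3L, n - 1L) else min(k, n - 1L)
      s <- knn_outlier_scores(v[ok], kk)
      score_rows[[p]] <- s
      idx_rows[[p]] <- ok
    }
    resid_all <- unlist(lapply(score_rows, function(s)
      if (is.null(s)) NULL else s - median(s)))
    if (is.null(resid_all) || length(resid_all) == 0) {
      flagged[[gi]] <- NULL
      next
    }
    scale <- .pooled_scale(resid_all)
    rows_flagged <- list()
    if (scale > 0) {
      for (p in seq_len(nrow(sub))) {
        s <- score_rows[[p]]
        if (is.null(s)) next
        z <- (s - median(s)) / scale
        hit <- which(z > z_threshold)
        if (length(hit)) {
          ok <- idx_rows[[p]]
          rows_flagged[[length(rows_flagged) + 1L]] <- data.frame(
            protein_id = rownames(matrix)[p],
            sample_id = colnames(sub)[ok[hit]],
            value = unname(sub[p, ok[hit]]),
            score = unname(s[hit])
          )
        }
      }
    }
    flagged[[gi]] <- if (length(rows_flagged))
      do.call(rbind, rows_flagged) else NULL
  }
  if (warn && length(skipped))
    warning("group(s) with < 3 non-missing values skipped for some ",
            "proteins: ", paste(unique(skipped), collapse = ", "))
  flagged <- do.call(rbind, c(list(.empty_flags()), flagged))
  rownames(flagged) <- NULL
  if (nrow(flagged)) {
    matrix[cbind(match(flagged$protein_id, rownames(matrix)),
                 match(flagged$sample_id, colnames(matrix)))] <- NA
  }
  list(matrix = matrix, flagged = flagged)
}
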