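#' Relative variance: between-group over pooled within-group variance
#'
#' The candidate-ranking score: sample variance of the group means
#' (denominator G - 1) divided by the pooled within-group sample variance.
#' Needs at least two groups with at least two non-missing values each;
#' otherwise returns `NA`. A zero pooled variance is guarded by
#' `epsilon` and the ratio capped at `cap`.
#'
#' @param values_by_group List of numeric vectors, one per experimental
#'   group.
#' @param epsilon Lower guard for the pooled within-group variance.
#' @param cap Upper cap for the ratio.
#' @return Nonnegative scalar (or `NA`).
#' @export
#' @examples
#' relative_variance(list(A = c(0, 2), B = c(2, 4)))  # 1
relative_variance <- function(values_by_group, epsilon = 1e-12,
                              cap = 1e12) {
  vals <- lapply(values_by_group, function(v) v[!is.na(v)])
  vals <- vals[vapply(vals, length, 1L) >= 2]
  if (length(vals) < 2) return(NA_real_)
  mu <- vapply(vals, mean, numeric(1))
  between <- var(mu)
  ns <- vapply(vals, length, 1L)
  within <- sum((ns - 1) * vapply(vals, var, numeric(1))) / sum(ns - 1)
  if (between == 0) return(0)
  min(between / max(within, epsilon), cap)
}

#' Select the top fraction of scores, keeping boundary ties
#'
#' Keeps the `ceiling(fraction * m)` largest scores (`m` = number of
#' non-missing scores); all scores tied with the boundary value are
#' included, so the selected count may exceed the nominal count (both are
#' reported).
#'
#' @param scores Numeric vector (`NA` = unscored, never selected).
#' @param fraction Fraction to retain (default 0.05).
#' @return List: `selected` (logical aligned with `scores`), `n_nominal`,
#'   `n_selected`, `threshold`.
#' @export
select_top_fraction <- function(scores, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  ok <- !is.na(scores)
  m <- sum(ok)
  if (m == 0)
    return(list(selected = rep(FALSE, length(scores)), n_nominal = 0L,
                n_selected = 0L, threshold = NA_real_))
  k <- as.integer(ceiling(fraction * m))
  thr <- sort(scores[ok], decreasing = TRUE)[k]
  sel <- ok & scores >= thr
  list(selected = sel, n_nominal = k, n_selected = sum(sel),
       threshold = thr)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` passed
#'   through).
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Rank proteins by relative variance and select candidates with FDR control
#'
#' Computes the relative variance of every protein across the
#' genotype-by-treatment cells, ranks proteins (dense rank, descending),
#' retains the top `fraction` (boundary ties included), and applies
#' Benjamini-Hochberg adjustment to the differential-test p-values of the
#' retained set (adjustment is deliberately deferred to this stage so the
#' preceding network exploration stays unadjusted).
#'
#' @param differential data.frame from [differential_table()] (needs
#'   protein_id and p_value).
#' @param matrix Numeric proteins x samples matrix the scores are computed
#'   on (typically normalized).
#' @param annotation Sample annotation data.frame.
#' @param fraction Fraction of proteins to retain (default 0.05).
#' @return data.frame: protein_id, relative_variance, rank (dense,
#'   descending, `NA` for unscored), selected, p_value, q_value (`NA`
#'   outside the selected set).
#' @export
candidate_table <- function(differential, matrix, annotation,
                            fraction = 0.05) {
  annotation <- validate_annotation(annotation, matrix)
  cells <- factor(paste(annotation$genotype, annotation$treatment,
                        sep = "."))
  rv <- vapply(seq_len(nrow(matrix)), function(p) {
    relative_variance(split(matrix[p, ], cells))
  }, numeric(1))
  ids <- rownames(matrix)
  sel <- select_top_fraction(rv, fraction)
  rank <- rep(NA_integer_, length(rv))
  ok <- !is.na(rv)
  rank[ok] <- match(-rv[ok], sort(unique(-rv[ok])))  # dense rank, descending
  out <- data.frame(protein_id = ids, relative_variance = rv, rank = rank,
                    selected = sel$selected)
  out$p_value <- differential$p_value[match(ids, differential$protein_id)]
  out$q_value <- NA_real_
  out$q_value[out$selected] <- bh_adjust(out$p_value[out$selected])
  attr(out, "n_nominal") <- sel$n_nominal
  attr(out, "threshold") <- sel$threshold
  out
}
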