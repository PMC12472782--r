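#' Fold change between case and control abundance vectors
#'
#' `fc = mean(case) / mean(control)` on available (non-missing) values, with
#' `log2fc = log2(fc)`. Returns `NA` for both when either mean is undefined
#' or non-positive (such proteins are reported as untested downstream).
#'
#' @param case_values,control_values Numeric vectors (missing allowed).
#' @return Named numeric vector `c(fc, log2fc)`.
#' @export
#' @examples
#' fold_change(c(1.2, 1.3), c(0.9, 1.1))
fold_change <- function(case_values, control_values) {
  mc <- mean(case_values, na.rm = TRUE)
  m0 <- mean(control_values, na.rm = TRUE)
  if (!is.finite(mc) || !is.finite(m0) || mc <= 0 || m0 <= 0)
    return(c(fc = NA_real_, log2fc = NA_real_))
  fc <- mc / m0
  c(fc = fc, log2fc = log2(fc))
}

#' Normality-routed two-group test
#'
#' Each group is screened with the Shapiro-Wilk test; if both pass at
#' `alpha_normality` the groups are compared with the classical
#' equal-variance Student's t-test, otherwise with the two-sided
#' Mann-Whitney U test (exact null distribution when both groups have at
#' most 8 values and no ties, normal approximation with continuity and tie
#' correction otherwise). Constant groups, on which Shapiro-Wilk is
#' undefined, are routed to Mann-Whitney; two identical constant groups are
#' degenerate and reported with `p = 1`. Groups with fewer than 3
#' non-missing values are not tested.
#'
#' @inheritParams fold_change
#' @param alpha_normality Shapiro-Wilk level used for routing (default
#'   0.05).
#' @return List with `test_used` (`"student_t"`, `"mann_whitney"` or
#'   `"untested"`), `p_value`, and `degenerate` flag.
#' @export
route_and_test <- function(case_values, control_values,
                           alpha_normality = 0.05) {
  a <- case_values[!is.na(case_values)]
  b <- control_values[!is.na(control_values)]
  if (length(a) < 3 || length(b) < 3)
    return(list(test_used = "untested", p_value = NA_real_,
                degenerate = FALSE))
  const_a <- length(unique(a)) == 1
  const_b <- length(unique(b)) == 1
  if (const_a && const_b && a[1] == b[1])
    return(list(test_used = "mann_whitney", p_value = 1, degenerate = TRUE))
  sw_p <- function(x) {
    if (length(unique(x)) == 1) return(0)          # constant: fail routing
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  normal <- sw_p(a) > alpha_normality && sw_p(b) > alpha_normality
  if (normal) {
    p <- t.test(a, b, var.equal = TRUE)$p.value
    return(list(test_used = "student_t", p_value = p, degenerate = FALSE))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
  list(test_used = "mann_whitney", p_value = p, degenerate = FALSE)
}

#' Volcano classification with asymmetric log2 fold-change cuts
#'
#' A protein is `up` when `p < p_cut`, `log2fc > up_cut` and the arithmetic
#' change `|fc - 1|` is at least `min_change`; `down` when `p < p_cut`,
#' `log2fc < down_cut` and the change condition holds; otherwise `ns`.
#' Defaults are the screening constants used throughout the pipeline:
#' p 0.05, cuts +0.32 / -0.41, minimum change 25%. Inequalities on p and
#' log2fc are strict; untested proteins are `ns`.
#'
#' @param log2fc,p_value,pct_change Numeric vectors (recycled to a common
#'   length); `pct_change = |fc - 1|`.
#' @param p_cut,up_cut,down_cut,min_change Classification constants.
#' @return Character vector in `c("up", "down", "ns")`.
#' @export
classify_volcano <- function(log2fc, p_value, pct_change, p_cut = 0.05,
                             up_cut = 0.32, down_cut = -0.41,
                             min_change = 0.25) {
  n <- max(length(log2fc), length(p_value), length(pct_change))
  log2fc <- rep_len(log2fc, n)
  p_value <- rep_len(p_value, n)
  pct_change <- rep_len(pct_change, n)
  out <- rep("ns", n)
  ok <- !is.na(log2fc) & !is.na(p_value) & !is.na(pct_change)
  up <- ok & p_value < p_cut & log2fc > up_cut & pct_change >= min_change
  dn <- ok & p_value < p_cut & log2fc < down_cut & pct_change >= min_change
  out[up] <- "up"
  out[dn] <- "down"
  out
}

#' Per-protein differential-abundance table for a two-group contrast
#'
#' Splits samples into case and control by the requested contrast --
#' `"genotype"` (TG vs WT control, optionally restricted to one treatment
#' arm, by default the vehicle arm) or `"treatment"` (DCI vs VEH control,
#' optionally within one genotype) -- then computes, per protein, group
#' means, fold change, the routed test p-value and the volcano class.
#'
#' @param matrix Numeric proteins x samples matrix (typically normalized).
#' @param annotation Sample annotation data.frame.
#' @param contrast `"genotype"` or `"treatment"`.
#' @param within Optional restriction: a treatment level for the genotype
#'   contrast (default `"VEH"`), or a genotype level for the treatment
#'   contrast (default `"TG"`). Use `NA` for no restriction.
#' @param alpha_normality Shapiro-Wilk routing level.
#' @inheritParams classify_volcano
#' @return data.frame with one row per protein: protein_id, mean_control,
#'   mean_case, fc, log2fc, pct_change, test_used, p_value, neg_log10_p,
#'   volcano_class.
#' @export
differential_table <- function(matrix, annotation,
                               contrast = c("genotype", "treatment"),
                               within = NULL, alpha_normality = 0.05,
                               p_cut = 0.05, up_cut = 0.32,
                               down_cut = -0.41, min_change = 0.25) {
  contrast <- match.arg(contrast)
  annotation <- validate_annotation(annotation, matrix)
  if (contrast == "genotype") {
    if (is.null(within)) within <- "VEH"
    keep <- if (is.na(within)) rep(TRUE, nrow(annotation))
            else annotation$treatment == within
    case <- keep & annotation$genotype == "TG"
    ctrl <- keep & annotation$genotype == "WT"
  } else {
    if (is.null(within)) within <- "TG"
    keep <- if (is.na(within)) rep(TRUE, nrow(annotation))
            else annotation$genotype == within
    case <- keep & annotation$treatment == "DCI"
    ctrl <- keep & annotation$treatment == "VEH"
  }
  if (!any(case) || !any(ctrl))
    stop("contrast has an empty case or control group")
  res <- lapply(seq_len(nrow(matrix)), function(p) {
    a <- matrix[p, case]
    b <- matrix[p, ctrl]
    fcv <- fold_change(a, b)
    tst <- if (is.na(fcv[["fc"]]))
      list(test_used = "untested", p_value = NA_real_, degenerate = FALSE)
    else route_and_test(a, b, alpha_normality)
    data.frame(
      protein_id = rownames(matrix)[p],
      mean_control = mean(b, na.rm = TRUE),
      mean_case = mean(a, na.rm = TRUE),
      fc = fcv[["fc"]], log2fc = fcv[["log2fc"]],
      pct_change = abs(fcv[["fc"]] - 1),
      test_used = tst$test_used, p_value = tst$p_value,
      neg_log10_p = -log10(tst$p_value)
    )
  })
  out <- do.call(rbind, res)
  out$volcano_class <- classify_volcano(out$log2fc, out$p_value,
                                        out$pct_change, p_cut, up_cut,
                                        down_cut, min_change)
  rownames(out) <- NULL
  out
}
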