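#' Default pipeline run configuration
#'
#' A nested list of stage parameters, defaulting to the screening constants
#' the pipeline is built around (p 0.05, log2FC cuts +0.32/-0.41, minimum
#' change 25%, top 5% relative variance, interaction-score cut 400) and the
#' study-design simulation conditions of [sim_config()]. Unknown keys in
#' `overrides` are rejected.
#'
#' @param seed Top-level seed; all stage randomness derives from it.
#' @param overrides Named nested list of values overriding the defaults.
#' @return List of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    input = list(matrix_path = NULL, annotation_path = NULL),
    simulate = list(enabled = TRUE, n_proteins = 2000L, n_per_cell = 6L,
                    cv = 0.2, effect_fraction = 0.35,
                    spike_fraction = 0.05,
                    baseline_log10_range = c(4, 9), depth_sigma = 0.2,
                    outlier_rate = 0.005, outlier_factor = 10,
                    sexes = TRUE),
    qc = list(enabled = TRUE, k = NULL, z_threshold = 20, by_sex = TRUE),
    normalize = list(method = "down_scaling", reference_ids = NULL,
                     by_sex = TRUE),
    diffexp = list(contrast = "genotype", within = "VEH",
                   alpha_normality = 0.05, p_cut = 0.05, up_cut = 0.32,
                   down_cut = -0.41, min_change = 0.25),
    select = list(fraction = 0.05),
    network = list(edges_path = NULL, min_score = 400L,
                   min_component = 3L),
    enrich = list(gmt_path = NULL, top_n = 20L),
    out_dir = NULL
  )
  merge_cfg <- function(base, over, path = "") {
    for (key in names(over)) {
      if (!key %in% names(base))
        stop("unknown config key: ", path, key)
      if (is.list(base[[key]]) && is.list(over[[key]]) &&
          !is.null(names(base[[key]])))
        base[[key]] <- merge_cfg(base[[key]], over[[key]],
                                 paste0(path, key, "$"))
      else base[key] <- over[key]
    }
    base
  }
  structure(merge_cfg(cfg, overrides), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [default_run_config()]; values present in the file override
#' the defaults, unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param seed Seed used when the file does not set one.
#' @return List of class `"run_config"`.
#' @export
read_run_config <- function(path, seed = 1L) {
  over <- yaml::read_yaml(path)
  if (!is.null(over$seed)) {
    seed <- over$seed
    over$seed <- NULL
  }
  default_run_config(seed = seed, overrides = over)
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate (or load) -> outlier QC -> normalization ->
#' differential testing -> candidate selection -> optional offline network
#' and enrichment reporting. With a fixed config and seed the run is fully
#' deterministic; when `out_dir` is set, every table is written as TSV with
#' a JSON provenance sidecar.
#'
#' @param config A `"run_config"` list from [default_run_config()] or
#'   [read_run_config()].
#' @return List of class `"run_report"`: `counts` (named integer summary),
#'   `tables` (matrix, annotation, truth, outliers, differential,
#'   candidates, components, enrichment), `config`, `elapsed` (seconds).
#' @export
#' @examples
#' cfg <- default_run_config(seed = 1, overrides = list(
#'   simulate = list(n_proteins = 100L, n_per_cell = 4L, sexes = FALSE)))
#' rep <- run_pipeline(cfg)
#' rep$counts
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$input$matrix_path)) {
    mat <- stage("input", read_abundance_matrix(config$input$matrix_path))
    ann <- stage("input", read_sample_annotation(
      config$input$annotation_path, mat))
  } else if (isTRUE(config$simulate$enabled)) {
    sim_args <- config$simulate
    sim_args$enabled <- NULL
    sim_args$seed <- config$seed
    sim <- stage("simulate", simulate_dataset(do.call(sim_config,
                                                      sim_args)))
    mat <- sim$matrix
    ann <- sim$annotation
    truth <- sim$truth
  } else {
    stop("no input: set input$matrix_path or enable the simulate stage")
  }
  n_in <- nrow(mat)

  flagged <- data.frame()
  if (isTRUE(config$qc$enabled)) {
    qc <- stage("qc", remove_outliers(mat, ann, k = config$qc$k,
                                      z_threshold = config$qc$z_threshold,
                                      by_sex = config$qc$by_sex))
    mat <- qc$matrix
    flagged <- qc$flagged
  }

  norm <- stage("normalize", normalize_abundance(
    mat, ann, method = config$normalize$method,
    reference_ids = config$normalize$reference_ids,
    by_sex = config$normalize$by_sex))
  mat_n <- norm$normalized

  de <- config$diffexp
  diff <- stage("diffexp", differential_table(
    mat_n, ann, contrast = de$contrast, within = de$within,
    alpha_normality = de$alpha_normality, p_cut = de$p_cut,
    up_cut = de$up_cut, down_cut = de$down_cut,
    min_change = de$min_change))

  cand <- stage("select", candidate_table(diff, mat_n, ann,
                                          fraction = config$select$fraction))

  components <- list()
  if (!is.null(config$network$edges_path)) {
    edges <- stage("network", read_string_edges(
      config$network$edges_path, min_score = config$network$min_score))
    sig <- diff$protein_id[diff$volcano_class != "ns"]
    components <- stage("network", induced_components(
      edges, sig, min_component = config$network$min_component))
  }

  enrichment <- NULL
  if (!is.null(config$enrich$gmt_path)) {
    gmt <- stage("enrich", read_gmt(config$enrich$gmt_path))
    sel <- cand$protein_id[cand$selected]
    enrichment <- stage("enrich", hypergeometric_enrichment(
      intersect(sel, rownames(mat_n)), gmt, rownames(mat_n),
      top_n = config$enrich$top_n))
  }

  counts <- c(
    proteins_in = n_in,
    outliers_flagged = nrow(flagged),
    tested = sum(diff$test_used != "untested"),
    up = sum(diff$volcano_class == "up"),
    down = sum(diff$volcano_class == "down"),
    candidates = sum(cand$selected),
    components = length(components),
    enriched_terms = if (is.null(enrichment)) 0L else nrow(enrichment)
  )

  report <- structure(list(
    counts = counts,
    tables = list(matrix = mat_n, annotation = ann, truth = truth,
                  outliers = flagged, differential = diff,
                  candidates = cand, components = components,
                  enrichment = enrichment),
    config = config,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write all pipeline outputs of a run to a directory
#' @param report A `"run_report"` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = report$config$seed)
  tb <- report$tables
  write_abundance_matrix(tb$matrix, file.path(out_dir, "matrix.tsv"),
                         provenance = prov)
  write_table_tsv(tb$annotation, file.path(out_dir, "annotation.tsv"),
                  provenance = prov)
  if (!is.null(tb$truth))
    write_table_tsv(tb$truth$proteins, file.path(out_dir, "truth.tsv"),
                    provenance = prov)
  write_table_tsv(tb$outliers, file.path(out_dir, "outliers.tsv"),
                  provenance = prov)
  write_table_tsv(tb$differential, file.path(out_dir, "differential.tsv"),
                  provenance = prov)
  write_table_tsv(tb$candidates, file.path(out_dir, "candidates.tsv"),
                  provenance = prov)
  if (length(tb$components)) {
    comp_df <- data.frame(
      component = rep(seq_along(tb$components),
                      lengths(tb$components)),
      protein_id = unlist(tb$components)
    )
    write_table_tsv(comp_df, file.path(out_dir, "components.tsv"),
                    provenance = prov)
  }
  if (!is.null(tb$enrichment))
    write_table_tsv(tb$enrichment, file.path(out_dir, "enrichment.tsv"),
                    provenance = prov)
  jsonlite::write_json(
    list(counts = as.list(report$counts), seed = report$config$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("prosieve pipeline run (seed ", x$config$seed, ")\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-17s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  elapsed           %.1f s\n", x$elapsed))
  invisible(x)
}
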