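#' Read a wide protein-abundance matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose first column holds protein
#' identifiers and whose header row holds sample identifiers. Empty cells and
#' `"NA"` are treated as missing. Parsing uses a dot decimal separator
#' regardless of locale.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (proteins x samples) with protein IDs as rownames
#'   and sample IDs as colnames; missing cells are `NA`.
#' @export
read_abundance_matrix <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "",
                     blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])
    stop("ragged rows in ", path, " at line(s): ",
         paste(bad, collapse = ", "))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("", "NA"), colClasses = "character",
                   quote = "", comment.char = "")
  if (ncol(df) < 3) stop("matrix must have at least 2 sample columns")
  ids <- df[[1]]
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate protein ID(s) at line(s): ",
         paste(dup + 1, collapse = ", "), " (",
         paste(unique(ids[dup]), collapse = ", "), ")")
  sids <- colnames(df)[-1]
  if (anyDuplicated(sids)) stop("duplicate sample IDs in header")
  vals <- vapply(df[-1], function(col) {
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(df)))
  if (nrow(df) == 1) vals <- matrix(vals, nrow = 1)
  unparsed <- which(is.na(vals) & !is.na(as.matrix(df[-1])), arr.ind = TRUE)
  if (nrow(unparsed))
    stop("non-numeric value at line ", unparsed[1, 1] + 1,
         ", sample ", sids[unparsed[1, 2]])
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance at line ", neg[1, 1] + 1,
         ", sample ", sids[neg[1, 2]])
  dimnames(vals) <- list(ids, sids)
  vals
}

#' Write an abundance matrix as TSV with a provenance sidecar
#'
#' Missing values are written as empty strings so the write/read round trip
#' preserves missingness. A JSON sidecar (`<path>.json`) records the tool
#' version and any parameters supplied.
#'
#' @param matrix Numeric proteins x samples matrix with dimnames.
#' @param path Output TSV path.
#' @param id_column Name for the first (protein ID) column.
#' @param provenance Named list recorded in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(matrix, path, id_column = "protein_id",
                                   provenance = list()) {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  write_provenance(path, provenance)
  invisible(path)
}

#' @keywords internal
write_provenance <- function(path, params = list()) {
  rec <- list(tool = "prosieve",
              version = as.character(packageVersion("prosieve")),
              file = basename(path), parameters = params)
  jsonlite::write_json(rec, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(NULL)
}

#' Read and cross-validate a sample annotation table
#'
#' The TSV must contain columns `sample_id`, `genotype` (`WT`/`TG`),
#' `treatment` (`VEH`/`DCI`) and `sex` (`M`/`F` or missing). Every sample in
#' `matrix` must be annotated exactly once; annotation rows without a
#' matching matrix column are dropped with a warning.
#'
#' @param path Path to the annotation TSV.
#' @param matrix Abundance matrix whose column names are validated against
#'   the table (optional; skip cross-validation when `NULL`).
#' @return data.frame with columns sample_id, genotype, treatment, sex,
#'   ordered as the matrix columns when a matrix is given.
#' @export
read_sample_annotation <- function(path, matrix = NULL) {
  ann <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = c("", "NA"), colClasses = "character",
                    quote = "", comment.char = "")
  validate_annotation(ann, matrix)
}

#' Validate a sample annotation data.frame against a matrix
#' @inheritParams read_sample_annotation
#' @param annotation data.frame with columns sample_id, genotype, treatment,
#'   sex.
#' @return The validated (and matrix-ordered) annotation data.frame.
#' @export
validate_annotation <- function(annotation, matrix = NULL) {
  need <- c("sample_id", "genotype", "treatment", "sex")
  miss <- setdiff(need, colnames(annotation))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  ann <- annotation[, need]
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
               collapse = ", "))
  bad_g <- setdiff(unique(ann$genotype), c("WT", "TG"))
  if (length(bad_g))
    stop("unknown genotype level(s): ", paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(ann$treatment), c("VEH", "DCI"))
  if (length(bad_t))
    stop("unknown treatment level(s): ", paste(bad_t, collapse = ", "))
  bad_s <- setdiff(unique(ann$sex[!is.na(ann$sex)]), c("M", "F"))
  if (length(bad_s))
    stop("unknown sex level(s): ", paste(bad_s, collapse = ", "))
  if (!is.null(matrix)) {
    unannotated <- setdiff(colnames(matrix), ann$sample_id)
    if (length(unannotated))
      stop("sample(s) without annotation: ",
           paste(unannotated, collapse = ", "))
    extra <- setdiff(ann$sample_id, colnames(matrix))
    if (length(extra)) {
      warning("dropping ", length(extra),
              " annotation row(s) not present in the matrix: ",
              paste(extra, collapse = ", "))
      ann <- ann[ann$sample_id %in% colnames(matrix), ]
    }
    ann <- ann[match(colnames(matrix), ann$sample_id), ]
  }
  rownames(ann) <- NULL
  ann
}

#' Write a sample annotation (or any data.frame) as TSV with sidecar
#' @param df data.frame to write.
#' @inheritParams write_abundance_matrix
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, provenance = list()) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  write_provenance(path, provenance)
  invisible(path)
}

# genotype x treatment (x sex where available) grouping factor
#' @keywords internal
sample_groups <- function(annotation, by_sex = TRUE) {
  g <- paste(annotation$genotype, annotation$treatment, sep = ".")
  if (by_sex && !all(is.na(annotation$sex)))
    g <- paste(g, annotation$sex, sep = ".")
  factor(g)
}
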