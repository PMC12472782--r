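# shared fixture builders and independent oracles

# tiny matrix with named dims
toy_matrix <- function(values, proteins = NULL, samples = NULL) {
  m <- if (is.matrix(values)) values else matrix(values,
                                                 nrow = length(proteins))
  if (is.null(proteins)) proteins <- sprintf("P%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(m)))
  dimnames(m) <- list(proteins, samples)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced annotation: n per genotype x treatment cell (per sex if given)
toy_annotation <- function(n_per_cell, sexes = FALSE) {
  sx <- if (sexes) c("M", "F") else NA_character_
  ann <- expand.grid(rep = seq_len(n_per_cell),
                     treatment = c("VEH", "DCI"),
                     genotype = c("WT", "TG"), sex = sx,
                     stringsAsFactors = FALSE)
  ann$sample_id <- paste0(ifelse(is.na(ann$sex), "S", ann$sex), "_",
                          ann$genotype, "_", ann$treatment, "_", ann$rep)
  ann[, c("sample_id", "genotype", "treatment", "sex")]
}

cell_key <- function(df) paste(df$protein_id, df$sample_id)

# exact two-sided Mann-Whitney p by exhaustive label enumeration (the U
# null is symmetric, so the symmetric-tail probability equals the
# two-sided doubling rule)
mw_enumeration_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  rk <- rank(x)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  centre <- n1 * length(b) / 2
  combs <- utils::combn(length(x), n1)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# independent Benjamini-Hochberg step-up: sort, scale by m/i, cumulative
# min from the largest, unsort
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}
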