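#' Read a protein-interaction edge table (STRING export dialect)
#'
#' Expects a TSV with header columns `protein1`, `protein2`,
#' `combined_score` (integer confidence, 0-1000). Self-loops are dropped
#' with a warning; duplicate undirected pairs are collapsed keeping the
#' maximum score; edges below `min_score` are discarded.
#'
#' @param path Path to the edge TSV.
#' @param min_score Minimum combined score retained (default 400, the
#'   conventional medium-confidence cut).
#' @return data.frame with columns protein1, protein2, combined_score; one
#'   row per undirected edge.
#' @export
read_string_edges <- function(path, min_score = 400) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "",
                   comment.char = "")
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("edge table is missing column(s): ", paste(miss, collapse = ", "))
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) | score < 0 | score > 1000 |
                 score != floor(score) | is.na(df$protein1) |
                 is.na(df$protein2) | df$protein1 == "" |
                 df$protein2 == "")
  if (length(bad))
    stop("malformed edge row(s) at line(s): ",
         paste(bad + 1, collapse = ", "))
  df$combined_score <- score
  loops <- df$protein1 == df$protein2
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s)")
    df <- df[!loops, ]
  }
  key <- ifelse(df$protein1 < df$protein2,
                paste(df$protein1, df$protein2, sep = "\r"),
                paste(df$protein2, df$protein1, sep = "\r"))
  ord <- order(key, -df$combined_score)
  df <- df[ord, ]
  key <- key[ord]
  df <- df[!duplicated(key), ]
  df <- df[df$combined_score >= min_score, ]
  rownames(df) <- NULL
  df[, need]
}

#' Connected components of the subgraph induced by significant proteins
#'
#' Restricts the interaction graph to the given protein set, extracts
#' connected components of size at least `min_component`, and returns them
#' largest-first (ties broken by the lexicographically smallest member);
#' members within a component are sorted.
#'
#' @param edges Edge data.frame from [read_string_edges()].
#' @param significant Character vector of protein IDs.
#' @param min_component Minimum component size reported (default 3).
#' @return List of character vectors (component members).
#' @export
induced_components <- function(edges, significant, min_component = 3) {
  nodes <- unique(c(edges$protein1, edges$protein2))
  keep <- intersect(significant, nodes)
  if (length(keep) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("protein1", "protein2")],
                                     directed = FALSE, vertices = nodes)
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  members <- members[lengths(members) >= min_component]
  if (length(members) == 0) return(list())
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1), 1))
  unname(members[ord])
}

#' Read a GMT annotation file into a named list of gene sets
#'
#' @param path Path to a gene-matrix-transposed (GMT) file.
#' @return Named list: term id -> character vector of member genes.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric term enrichment with per-category FDR ranking
#'
#' For each annotation term, tests over-representation of the selected
#' protein set within the universe using the upper hypergeometric tail
#' `P(X >= overlap)`; term gene sets are first intersected with the
#' universe. Benjamini-Hochberg q-values and ranks are computed within each
#' category; all terms are returned, with the conventional top-20-by-FDR
#' report available through `top_n`.
#'
#' @param selected Character vector of selected proteins (must be a subset
#'   of `universe`).
#' @param annotations Named list of gene sets (term -> members), or a named
#'   list of such lists keyed by category (e.g. BP/CC/MF/KEGG).
#' @param universe Character vector of all quantified proteins.
#' @param top_n When non-`NULL`, keep only the `top_n` lowest-q terms per
#'   category (default `NULL` = all).
#' @return data.frame: term_id, category, universe_size, term_size,
#'   selected_size, overlap, p_value, q_value, rank.
#' @export
hypergeometric_enrichment <- function(selected, annotations, universe,
                                      top_n = NULL) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stop("selected proteins must be a subset of the universe")
  if (length(annotations) && !is.list(annotations[[1]]))
    annotations <- list(custom = annotations)
  rows <- lapply(names(annotations), function(cat) {
    sets <- annotations[[cat]]
    recs <- lapply(names(sets), function(term) {
      members <- intersect(sets[[term]], universe)
      ov <- length(intersect(members, selected))
      p <- phyper(ov - 1, length(members),
                  length(universe) - length(members), length(selected),
                  lower.tail = FALSE)
      data.frame(term_id = term, category = cat,
                 universe_size = length(universe),
                 term_size = length(members),
                 selected_size = length(selected),
                 overlap = ov, p_value = p)
    })
    df <- do.call(rbind, recs)
    df$q_value <- bh_adjust(df$p_value)
    df <- df[order(df$q_value, df$p_value, df$term_id), ]
    df$rank <- seq_len(nrow(df))
    if (!is.null(top_n)) df <- df[df$rank <= top_n, ]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
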