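write_edges <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", rows), f)
  f
}

test_that("edge tables are filtered, deduplicated and validated", {
  f <- write_edges(c("A\tB\t900", "B\tC\t500", "C\tD\t150"))
  g <- read_string_edges(f, min_score = 0)
  expect_equal(nrow(g), 3)
  expect_equal(nrow(read_string_edges(f, min_score = 400)), 2)
  expect_equal(nrow(read_string_edges(f, min_score = 700)), 1)
  # reversed duplicate collapses to one edge keeping the max score
  f2 <- write_edges(c("A\tB\t300", "B\tA\t800"))
  g2 <- read_string_edges(f2, min_score = 0)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$combined_score, 800)
  expect_warning(read_string_edges(write_edges("A\tA\t500"), 0),
                 "self-loop")
  expect_error(read_string_edges(write_edges("A\tB\t2000"), 0), "line")
  expect_error(read_string_edges(write_edges("A\tB\thigh"), 0), "line")
})

test_that("induced components follow the documented selection and order", {
  f <- write_edges(c("A\tB\t500", "B\tC\t500", "C\tD\t500"))
  edges <- read_string_edges(f, min_score = 0)
  # min_component 2: D is isolated once C is excluded
  comp <- induced_components(edges, c("A", "B", "D"), min_component = 2)
  expect_equal(comp, list(c("A", "B")))
  expect_equal(induced_components(edges, character(0)), list())
  # full node set: single component of the whole graph
  comp_all <- induced_components(edges, c("A", "B", "C", "D"),
                                 min_component = 3)
  expect_equal(comp_all, list(c("A", "B", "C", "D")))
  # two components ordered by size then smallest member; partition property
  f3 <- write_edges(c("X\tY\t500", "A\tB\t500", "B\tC\t500", "C\tA\t500",
                      "Y\tZ\t500", "Z\tX\t500"))
  e3 <- read_string_edges(f3, min_score = 0)
  comp3 <- induced_components(e3, c("A", "B", "C", "X", "Y", "Z"),
                              min_component = 3)
  expect_equal(comp3, list(c("A", "B", "C"), c("X", "Y", "Z")))
  expect_equal(sort(unlist(comp3)), c("A", "B", "C", "X", "Y", "Z"))
})

test_that("hypergeometric p matches the enumerated draw probability", {
  uni <- paste0("G", 1:10)
  terms <- list(T1 = uni[1:4])
  sel <- uni[1:5]  # overlap 4 of term size 4
  rec <- hypergeometric_enrichment(sel, terms, uni)
  expect_equal(rec$overlap, 4)
  expect_equal(rec$p_value, 6 / 252)  # C(4,4)*C(6,1)/C(10,5)
  # zero overlap with a small term and term = universe boundary cases
  rec0 <- hypergeometric_enrichment(uni[5:6], list(T = uni[1:2]), uni)
  expect_lte(rec0$p_value, 1)
  expect_equal(rec0$overlap, 0)
  recU <- hypergeometric_enrichment(uni[1:3], list(T = uni), uni)
  expect_equal(recU$p_value, 1)
  expect_error(hypergeometric_enrichment("X", terms, character(0)),
               "universe")
  expect_error(hypergeometric_enrichment("X", terms, uni), "subset")
})

test_that("enrichment ranks within category and respects top_n", {
  set.seed(21)
  uni <- paste0("G", 1:60)
  sel <- uni[1:12]
  mk <- function(n) replicate(n, sample(uni, 8), simplify = FALSE)
  ann <- list(BP = setNames(mk(25), paste0("bp", 1:25)),
              KEGG = setNames(mk(5), paste0("kegg", 1:5)))
  full <- hypergeometric_enrichment(sel, ann, uni)
  expect_equal(sort(unique(full$category)), c("BP", "KEGG"))
  for (cat in c("BP", "KEGG")) {
    sub <- full[full$category == cat, ]
    expect_equal(sub$rank, seq_len(nrow(sub)))
    expect_false(is.unsorted(sub$q_value))
    expect_equal(sub$q_value, bh_oracle(sub$p_value), tolerance = 1e-12)
  }
  top <- hypergeometric_enrichment(sel, ann, uni, top_n = 20)
  expect_equal(sum(top$category == "BP"), 20)
  expect_equal(sum(top$category == "KEGG"), 5)
})

test_that("GMT files round-trip into named gene-set lists", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tA\tB\tC", "term2\tdesc\tB\tD"), f)
  gmt <- read_gmt(f)
  expect_equal(gmt$term1, c("A", "B", "C"))
  expect_equal(gmt$term2, c("B", "D"))
})

test_that("enrichment p is invariant under relabelling of genes", {
  set.seed(31)
  uni <- paste0("G", 1:40)
  term <- sample(uni, 10)
  sel <- sample(uni, 8)
  p1 <- hypergeometric_enrichment(sel, list(T = term), uni)$p_value
  relabel <- setNames(paste0("H", 1:40), uni)
  p2 <- hypergeometric_enrichment(unname(relabel[sel]),
                                  list(T = unname(relabel[term])),
                                  unname(relabel))$p_value
  expect_equal(p1, p2)
})
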