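mk_expr <- function(values) {
  # values: named list gene -> numeric vector over (JH reps, JV reps)
  n <- length(values[[1]]) / 2
  dplyr::bind_rows(lapply(names(values), function(g) {
    tibble::tibble(
      transcript_id = g,
      condition = rep(c("JH", "JV"), each = n),
      replicate = rep(seq_len(n), 2),
      fpkm = values[[g]]
    )
  }))
}

test_that("a candidate identical to the query maxes GO and PCC scores", {
  ex <- mk_expr(list(q = c(1, 2, 3, 4, 5, 6), c1 = c(1, 2, 3, 4, 5, 6)))
  ann <- tibble::tibble(
    transcript_id = c("q", "c1"), go_term = "GO:1"
  )
  cs <- component_scores("q", "c1", ex, ann)
  expect_equal(cs$go_score, 1)
  expect_equal(cs$pcc_score, 1)
  expect_equal(cs$abundance_score, 1) # single candidate
})

test_that("disjoint annotation sets give a zero GO score", {
  ex <- mk_expr(list(q = 1:6, c1 = c(2, 1, 4, 3, 6, 5)))
  ann <- tibble::tibble(
    transcript_id = c("q", "c1"), go_term = c("GO:1", "GO:2")
  )
  expect_equal(component_scores("q", "c1", ex, ann)$go_score, 0)
  # and no annotations at all behave the same
  expect_equal(component_scores("q", "c1", ex, NULL)$go_score, 0)
})

test_that("abundance is rank-normalized across the candidate pool", {
  ex <- mk_expr(list(
    q = rep(1, 6), lo = rep(1, 6), mid = rep(10, 6), hi = rep(100, 6)
  ))
  cs <- component_scores("q", c("lo", "mid", "hi"), ex, NULL)
  expect_equal(
    cs$abundance_score[match(c("lo", "mid", "hi"), cs$candidate_gene)],
    c(0, 0.5, 1)
  )
})

test_that("missing expression is reported by gene name", {
  ex <- mk_expr(list(q = 1:6))
  expect_error(component_scores("nope", NULL, ex), "nope")
  expect_error(component_scores("q", "ghost", ex), "ghost")
})

test_that("the combined score is the exact weighted sum", {
  expect_equal(combined_score(c(1, 1, 1)), 1.0)
  expect_equal(combined_score(c(0, 0, 0)), 0.0)
  expect_equal(combined_score(c(0.5, 1, 0)), 0.5)
  expect_error(combined_score(c(1, 1, 1), weights = c(0.5, 0.3, 0.3)), "sum to 1")
  # monotone in each component under positive weights
  base <- combined_score(c(0.2, 0.4, 0.6))
  expect_gt(combined_score(c(0.3, 0.4, 0.6)), base)
  expect_gt(combined_score(c(0.2, 0.5, 0.6)), base)
  expect_gt(combined_score(c(0.2, 0.4, 0.7)), base)
})

test_that("neighbourhoods truncate at k with deterministic tie-breaks", {
  recs <- tibble::tibble(
    query_gene = "q",
    candidate_gene = sprintf("g%02d", 1:50),
    combined = rep(c(0.9, 0.5), c(10, 40))
  )
  expect_equal(nrow(top_k_neighbors(recs, 20L)), 20L)
  expect_equal(nrow(top_k_neighbors(recs[1:5, ], 20L)), 5L)
  # the tie at the boundary resolves by ascending gene id
  kept <- top_k_neighbors(recs, 20L)
  tied <- dplyr::filter(kept, combined == 0.5)
  expect_equal(tied$candidate_gene, sprintf("g%02d", 11:20))
})

test_that("the merged network deduplicates nodes and is reproducible", {
  withr::with_seed(51, {
    vals <- setNames(
      lapply(1:12, function(i) stats::runif(6, 1, 100)),
      c("q1", "q2", sprintf("c%02d", 1:10))
    )
    ex <- mk_expr(vals)
    net1 <- build_coexpression_network(c("q1", "q2"), ex, k = 4L)
    net2 <- build_coexpression_network(c("q1", "q2"), ex, k = 4L)
    expect_equal(net1$records, net2$records)
    expect_equal(igraph::ecount(net1$graph), 8L)
    expect_lte(igraph::vcount(net1$graph), 2L + 8L)
    expect_false(igraph::is_directed(net1$graph))
  })
  expect_warning(
    empty <- build_coexpression_network(character(0), mk_expr(list(a = 1:6))),
    "empty query"
  )
  expect_equal(igraph::vcount(empty$graph), 0L)
})

test_that("a small candidate pool keeps every candidate", {
  ex <- mk_expr(list(q = 1:6, a = 2:7, b = 3:8))
  net <- build_coexpression_network("q", ex, k = 20L)
  expect_equal(igraph::ecount(net$graph), 2L)
})
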