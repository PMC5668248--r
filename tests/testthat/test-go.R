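chain_dag <- function() {
  mirframe:::new_go_dag(
    tibble::tibble(
      id = c("g1", "g2"), name = c("parent", "child"), namespace = "BP"
    ),
    tibble::tibble(child = "g2", parent = "g1")
  )
}

test_that("node scores decay annotation counts down the DAG", {
  dag <- chain_dag()
  # leaf term: only distance 0 contributes, whatever alpha
  expect_equal(node_score(dag, "g2", c(g2 = 5), alpha = 0.3), 5)
  expect_equal(node_score(dag, "g2", c(g2 = 5), alpha = 1), 5)
  # chain: gp(parent) = 1, gp(child) = 2, alpha 0.5 -> 1 + 2 * 0.5
  expect_equal(node_score(dag, "g1", c(g1 = 1, g2 = 2), alpha = 0.5), 2.0)
  expect_error(node_score(dag, "nope", c(g1 = 1)), "unknown")
  expect_error(node_score(dag, "g1", c(g1 = 1), alpha = 0), "alpha")
})

test_that("at alpha = 1 the node score is the subtree annotation total", {
  for (sd in c(3, 14, 15)) {
    sim <- make_go(simulation_config(seed = sd))
    counts <- setNames(sim$truth_counts$gp, sim$truth_counts$go_term)
    for (term in sample(sim$dag$terms$id, 8)) {
      expect_equal(
        node_score(sim$dag, term, counts, alpha = 1),
        oracle_subtree_total(sim$dag, term, counts),
        info = paste(sd, term)
      )
    }
  }
})

test_that("node scores are monotone non-decreasing in alpha", {
  sim <- make_go(simulation_config(seed = 8))
  counts <- setNames(sim$truth_counts$gp, sim$truth_counts$go_term)
  root <- setdiff(sim$dag$terms$id, sim$dag$edges$child)[1]
  alphas <- c(0.2, 0.4, 0.6, 0.8, 1)
  scores <- vapply(
    alphas, function(a) node_score(sim$dag, root, counts, alpha = a),
    numeric(1)
  )
  expect_true(all(diff(scores) >= 0))
})

test_that("transcript scores sum their annotated terms, deduplicated", {
  dag <- chain_dag()
  ann <- tibble::tibble(transcript_id = "tx1", go_term = "g2")
  sc <- score_transcripts(dag, ann)
  expect_equal(sc$score, 1) # one leaf annotation, gp = 1
  dup <- dplyr::bind_rows(ann, ann)
  expect_equal(score_transcripts(dag, dup), sc)
  # a transcript with no annotation in the namespace scores 0 with a note
  dag_mf <- mirframe:::new_go_dag(
    tibble::tibble(
      id = c("g1", "g2", "m1"), name = "x", namespace = c("BP", "BP", "MF")
    ),
    tibble::tibble(child = "g2", parent = "g1")
  )
  ann2 <- tibble::tibble(
    transcript_id = c("tx1", "tx2"), go_term = c("g2", "m1")
  )
  expect_message(
    sc2 <- score_transcripts(dag_mf, ann2, namespace = "BP"),
    "score 0"
  )
  expect_equal(sc2$score[sc2$transcript_id == "tx2"], 0)
})

test_that("score clustering partitions transcripts deterministically", {
  scores <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    score = c(5, 3, 3, 1)
  )
  ann <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    go_term = c("g1", "g2", "g2", "g9")
  )
  cl <- cluster_by_score(scores, ann, tolerance = 0)
  expect_equal(nrow(cl$members), 3L)
  # every transcript in exactly one cluster
  expect_equal(sort(cl$clusters$transcript_id), c("a", "b", "c", "d"))
  expect_equal(anyDuplicated(cl$clusters$transcript_id), 0L)
  # identical scores share a cluster, labels ordered by descending score
  bc <- dplyr::filter(cl$clusters, transcript_id %in% c("b", "c"))
  expect_equal(length(unique(bc$cluster)), 1L)
  expect_equal(cl$members$cluster, c("C1", "C2", "C3"))
  # clusters sharing no terms get weight 0
  w <- dplyr::filter(cl$edges, from == "C1", to == "C3")
  expect_equal(w$weight, 0)
  # all-distinct scores at tolerance 0 -> singletons
  singl <- cluster_by_score(
    tibble::tibble(transcript_id = c("x", "y"), score = c(2, 1)),
    tolerance = 0
  )
  expect_equal(nrow(singl$members), 2L)
})

test_that("cluster filtering is monotone in the score threshold", {
  sim <- make_go(simulation_config(seed = 12))
  sc <- suppressMessages(score_transcripts(sim$dag, sim$annotations))
  cl <- cluster_by_score(sc, sim$annotations)
  expect_equal(nrow(filter_top_nodes(cl, 0)$members), nrow(cl$members))
  hi <- max(cl$members$score)
  expect_equal(nrow(filter_top_nodes(cl, hi + 1)$members), 0L)
  thresholds <- sort(c(0, cl$members$score))
  sizes <- vapply(
    thresholds,
    function(t) nrow(filter_top_nodes(cl, t)$members), integer(1)
  )
  expect_true(all(diff(sizes) <= 0))
})
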