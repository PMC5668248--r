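test_that("the generator is fully deterministic under a seed", {
  cfg <- simulation_config(seed = 99)
  t1 <- make_transcriptome(cfg)
  t2 <- make_transcriptome(cfg)
  expect_identical(t1, t2)
  e1 <- make_expression(cfg)
  e2 <- make_expression(cfg)
  expect_identical(e1, e2)
  g1 <- make_go(cfg)
  g2 <- make_go(cfg)
  expect_identical(g1, g2)
  # different seeds move the random parts
  t3 <- make_transcriptome(simulation_config(seed = 100))
  expect_false(identical(t1$transcripts$sequence, t3$transcripts$sequence))
})

test_that("truth tables carry planted coordinates and intended verdicts", {
  tx <- make_transcriptome(simulation_config(seed = 17))
  truth <- tx$truth_precursors
  expect_true(all(c(
    "is_candidate", "has_hairpin", "mature_in_one_arm",
    "duplex_mismatch_ok", "no_loop_or_break", "mfe_ok"
  ) %in% names(truth)))
  # the planted mature really sits at the recorded coordinates
  for (r in seq_len(nrow(truth))) {
    seq <- tx$transcripts$sequence[
      tx$transcripts$id == truth$transcript_id[r]
    ]
    mature <- tx$mature$sequence[tx$mature$id == truth$mature_id[r]]
    expect_equal(
      substr(seq, truth$mature_start[r], truth$mature_end[r]), mature
    )
  }
  # planted target sites are exact reverse complements in place
  for (r in seq_len(nrow(tx$truth_sites))) {
    seq <- tx$transcripts$sequence[
      tx$transcripts$id == tx$truth_sites$transcript_id[r]
    ]
    m <- tx$mature$sequence[tx$mature$id == tx$truth_sites$mirna_id[r]]
    expect_equal(
      substr(seq, tx$truth_sites$site_start[r], tx$truth_sites$site_end[r]),
      rev_comp(m)
    )
  }
})

test_that("expression output is non-negative with the planted structure", {
  cfg <- simulation_config(seed = 5, n_replicates = 6)
  ex <- make_expression(cfg)
  expect_true(all(ex$expression$fpkm >= 0))
  expect_equal(
    sort(unique(ex$expression$condition)), sort(cfg$conditions)
  )
  counts <- dplyr::count(ex$expression, transcript_id, condition)
  expect_true(all(counts$n == 6L))
  # grouped genes are recorded in the truth table
  expect_equal(
    sum(!is.na(ex$truth_groups$group)),
    cfg$coexpr_groups * cfg$group_size
  )
})

test_that("zero noise makes within-group correlation exactly one", {
  cfg <- simulation_config(seed = 6, fpkm_sigma = 0)
  ex <- make_expression(cfg)
  g1 <- ex$truth_groups$gene[which(ex$truth_groups$group == 1L)]
  wide <- tidyr::pivot_wider(
    dplyr::filter(ex$expression, transcript_id %in% g1[1:2]),
    id_cols = c("condition", "replicate"),
    names_from = "transcript_id", values_from = "fpkm"
  )
  expect_equal(stats::cor(wide[[3]], wide[[4]]), 1)
})

test_that("a depth-1 DAG is a star and synthetic DAGs are acyclic", {
  star <- make_go(simulation_config(seed = 2, dag_depth = 1L, n_go_terms = 8L))
  root <- setdiff(star$dag$terms$id, star$dag$edges$child)
  expect_equal(length(root), 1L)
  expect_true(all(star$dag$edges$parent == root))
  for (sd in 1:5) {
    sim <- make_go(simulation_config(seed = sd))
    g <- igraph::graph_from_data_frame(
      sim$dag$edges,
      directed = TRUE, vertices = sim$dag$terms$id
    )
    expect_true(igraph::is_dag(g))
  }
})

test_that("the root node score at alpha 1 equals the annotation total", {
  sim <- make_go(simulation_config(seed = 30, dag_depth = 1L, n_go_terms = 10L))
  counts <- setNames(sim$truth_counts$gp, sim$truth_counts$go_term)
  root <- setdiff(sim$dag$terms$id, sim$dag$edges$child)
  expect_equal(
    node_score(sim$dag, root, counts, alpha = 1),
    nrow(sim$annotations)
  )
})
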