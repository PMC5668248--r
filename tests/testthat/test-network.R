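star_graph <- function(n_leaves) {
  igraph::graph_from_data_frame(
    data.frame(from = "hub", to = paste0("leaf", seq_len(n_leaves))),
    directed = FALSE
  )
}

test_that("interaction matrices follow the 0/1 membership rule", {
  empty <- build_adjacency(tibble::tibble(
    mirna = character(), target = character()
  ))
  expect_equal(dim(empty), c(0L, 0L))

  A <- build_adjacency(tibble::tibble(
    mirna = c("m1", "m1"), target = c("t1", "t2")
  ))
  expect_equal(unname(A["m1", ]), c(1L, 1L))

  fx <- load_fixture_tables()
  jh <- fixture_condition_targets(fx, "JH")
  Afx <- build_adjacency(jh[, c("mirna", "target")])
  expect_equal(
    Afx["miR-156", "choline monooxygenase [EC:1.14.15.7]"], 1L
  )
})

test_that("bipartite networks separate the two node sets", {
  A <- diag(2L)
  dimnames(A) <- list(c("m1", "m2"), c("t1", "t2"))
  bip <- build_bipartite(A, "JH")
  expect_equal(igraph::vcount(bip$graph), 4L)
  expect_equal(igraph::ecount(bip$graph), 2L)
  expect_equal(igraph::ecount(bip$graph), sum(A))
  el <- igraph::as_edgelist(bip$graph)
  side <- setNames(igraph::V(bip$graph)$side, igraph::V(bip$graph)$name)
  expect_true(all(side[el[, 1]] == "mirna"))
  expect_true(all(side[el[, 2]] == "target"))
})

test_that("the three fixture network variants are constructible", {
  fx <- load_fixture_tables()
  jh <- fixture_condition_targets(fx, "JH")
  jv <- fixture_condition_targets(fx, "JV")
  cmp <- suppressWarnings(compare_conditions(jh, jv))
  jh_unique <- build_bipartite(
    dplyr::filter(jh, mirna %in% cmp$unique_mirnas_a), "JH"
  )
  jv_unique <- build_bipartite(
    dplyr::filter(jv, mirna %in% cmp$unique_mirnas_b), "JV"
  )
  common_diff <- build_bipartite(
    dplyr::bind_rows(
      dplyr::filter(jh, mirna %in% cmp$common_mirnas),
      dplyr::filter(jv, mirna %in% cmp$common_mirnas)
    ),
    "common"
  )
  expect_gt(igraph::ecount(jh_unique$graph), 0L)
  expect_gt(igraph::ecount(jv_unique$graph), 0L)
  expect_gt(igraph::ecount(common_diff$graph), 0L)
  # round trip through GraphML conserves the edge count
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(common_diff, gml, format = "graphml")
  expect_equal(
    igraph::ecount(read_network(gml, "graphml")),
    igraph::ecount(common_diff$graph)
  )
})

test_that("condition comparison splits families and calls regulation", {
  fx <- load_fixture_tables()
  jh <- fixture_condition_targets(fx, "JH")
  jv <- fixture_condition_targets(fx, "JV")
  cmp <- suppressWarnings(compare_conditions(jh, jv))
  expect_equal(
    cmp$common_mirnas,
    sort(c(
      "miR-156", "miR-157", "miR-159", "miR-319", "miR-4995",
      "miR-5021", "miR-5658", "miR-f11908"
    ))
  )
  expect_equal(cmp$unique_mirnas_a, sort(c("miR-172", "miR-414", "miR-529")))
  expect_equal(
    cmp$unique_mirnas_b,
    sort(c("miR-2910", "miR-2914", "miR-477", "miR-f11953", "miR-f12158"))
  )
  cmo <- dplyr::filter(
    cmp$common_targets,
    target_key == "choline monooxygenase"
  )
  expect_equal(cmo$regulation, "up")
})

test_that("comparison is symmetric and trivial on identical inputs", {
  fx <- load_fixture_tables()
  jh <- fixture_condition_targets(fx, "JH")
  jv <- fixture_condition_targets(fx, "JV")
  ab <- suppressWarnings(compare_conditions(jh, jv))
  ba <- suppressWarnings(compare_conditions(jv, jh))
  expect_equal(ab$unique_mirnas_a, ba$unique_mirnas_b)
  expect_equal(ab$unique_mirnas_b, ba$unique_mirnas_a)
  flip <- c(up = "down", down = "up", unchanged = "unchanged", unknown = "unknown")
  merged <- dplyr::left_join(
    ab$common_targets[, c("target_key", "regulation")],
    ba$common_targets[, c("target_key", "regulation")],
    by = "target_key"
  )
  expect_equal(unname(flip[merged$regulation.x]), merged$regulation.y)

  same <- compare_conditions(jh, jh)
  expect_equal(length(same$unique_mirnas_a), 0L)
  expect_equal(length(same$unique_mirnas_b), 0L)
})

test_that("the one discrepant fixture regulation arrow is reported", {
  bad <- suppressMessages(validate_fixture_regulation())
  expect_equal(bad$row_id, "6.5")
  expect_equal(bad$computed, "up")
  expect_equal(bad$printed, "down")
})

test_that("degree profiles normalize p(k) over the undirected view", {
  prof <- degree_profile(star_graph(4))
  hub <- dplyr::filter(prof$degrees, node == "hub")
  expect_equal(hub$degree, 4L)
  expect_equal(
    prof$distribution$p[prof$distribution$k == 1L], 0.8
  )
  expect_equal(
    prof$distribution$p[prof$distribution$k == 4L], 0.2
  )
  expect_equal(nrow(degree_profile(igraph::make_empty_graph())$degrees), 0L)
  withr::with_seed(41, {
    for (i in 1:10) {
      g <- igraph::sample_gnp(sample(3:12, 1), 0.4)
      expect_equal(sum(degree_profile(g)$distribution$p), 1)
    }
  })
})

test_that("degree correlation matches the endpoint-degree Pearson oracle", {
  expect_equal(degree_correlation(star_graph(4))$r, -1)
  expect_equal(degree_correlation(star_graph(2))$r, -1)
  path3 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c")),
    directed = FALSE
  )
  expect_equal(degree_correlation(path3)$r, -1)
  ring <- igraph::make_ring(5)
  expect_message(
    r_ring <- degree_correlation(ring)$r, "undefined"
  )
  expect_true(is.na(r_ring))
  expect_error(degree_correlation(igraph::make_empty_graph(3)), "edge")
  withr::with_seed(42, {
    done <- 0
    while (done < 12) {
      g <- igraph::sample_gnp(sample(4:10, 1), 0.5)
      if (igraph::ecount(g) < 2) next
      orc <- oracle_assortativity(g)
      if (is.na(orc)) next
      res <- degree_correlation(g)
      expect_equal(res$r, orc, tolerance = 1e-10)
      expect_equal(res$r, igraph::assortativity_degree(g), tolerance = 1e-10)
      done <- done + 1
    }
  })
})

test_that("expression PCC handles both modes and degenerate input", {
  ex <- tibble::tibble(
    transcript_id = "g1",
    condition = rep(c("JH", "JV"), each = 4),
    replicate = rep(1:4, 2),
    fpkm = c(1, 2, 3, 4, 2, 4, 6, 8)
  )
  expect_equal(expression_pcc(ex, "g1", "JH", "JV"), 1)
  neg <- ex
  neg$fpkm[5:8] <- 10 - c(1, 2, 3, 4)
  expect_equal(expression_pcc(neg, "g1", "JH", "JV"), -1)
  flat <- ex
  flat$fpkm[1:4] <- 5
  expect_message(
    r <- expression_pcc(flat, "g1", "JH", "JV"), "zero variance"
  )
  expect_true(is.na(r))
  short <- dplyr::filter(ex, replicate == 1)
  expect_error(
    expression_pcc(short, "g1", "JH", "JV"), "profile"
  )
  # cross-transcript profile mode over condition means
  prof <- tibble::tibble(
    transcript_id = rep(c("g1", "g2", "g3"), each = 2),
    condition = rep(c("JH", "JV"), 3),
    replicate = 1L,
    fpkm = c(1, 2, 5, 9, 20, 41)
  )
  expect_gt(
    expression_pcc(prof,
      condition_a = "JH", condition_b = "JV",
      mode = "profile"
    ), 0.99
  )
})

test_that("the packaged selection rule recovers the curated query genes", {
  fx <- load_fixture_tables()
  cmp <- suppressWarnings(compare_conditions(
    fixture_condition_targets(fx, "JH"),
    fixture_condition_targets(fx, "JV")
  ))
  sel <- select_pcc_genes(cmp, rule = "packaged")
  expect_setequal(
    sel$gene,
    c(
      "CMO", "RPS5", "RPL9", "EIF5", "MVA1", "PPC", "PSAX", "SUMO",
      "CYP707A1", "DXS"
    )
  )
  expect_equal(sel$mirnas[sel$gene == "CMO"], "miR-156;miR-157")
  expect_equal(sel$mirnas[sel$gene == "EIF5"], "miR-5021;miR-5658")
  both <- select_pcc_genes(cmp, rule = "both_conditions")
  expect_true(all(c("CMO", "RPS5", "EIF5", "MVA1") %in% both$gene))
  expect_false("PPC" %in% both$gene) # quantified in one condition only
  all_rule <- select_pcc_genes(cmp, rule = "all")
  expect_equal(nrow(all_rule), nrow(cmp$common_targets))
})
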