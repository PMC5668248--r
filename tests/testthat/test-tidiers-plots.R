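test_that("tidy and glance cover the main result objects", {
  f <- fold_rna("GGGGGAAAACCCCC")
  td <- tidy(f)
  expect_equal(nrow(td), 14L)
  expect_true(all(c("position", "base", "partner", "arm") %in% names(td)))
  expect_equal(glance(f)$mfe, f$mfe)

  bip <- build_bipartite(tibble::tibble(
    mirna = c("m1", "m1", "m2"), target = c("t1", "t2", "t1")
  ), "JH")
  expect_equal(nrow(tidy(bip)), 3L)
  gl <- glance(bip)
  expect_equal(gl$n_mirnas, 2L)
  expect_equal(gl$n_targets, 2L)
  expect_equal(gl$n_edges, 3L)

  dc <- degree_correlation(bip)
  expect_equal(nrow(tidy(dc)), 3L)
  expect_equal(glance(dc)$m, 3L)

  fx <- load_fixture_tables()
  cmp <- suppressWarnings(compare_conditions(
    fixture_condition_targets(fx, "JH"),
    fixture_condition_targets(fx, "JV")
  ))
  expect_equal(glance(cmp)$n_common_mirnas, 8L)
  expect_true("regulation" %in% names(tidy(cmp)))
})

test_that("autoplot methods return ggplot objects", {
  f <- fold_rna("GGGGGAAAACCCCC")
  expect_s3_class(autoplot(f), "ggplot")

  bip <- build_bipartite(tibble::tibble(
    mirna = c("m1", "m2"), target = c("t1", "t1")
  ))
  expect_s3_class(autoplot(bip), "ggplot")
  expect_s3_class(autoplot(degree_profile(bip)), "ggplot")

  fx <- load_fixture_tables()
  cmp <- suppressWarnings(compare_conditions(
    fixture_condition_targets(fx, "JH"),
    fixture_condition_targets(fx, "JV")
  ))
  expect_s3_class(autoplot(cmp), "ggplot")

  ex <- tibble::tibble(
    transcript_id = rep(c("q", "a", "b"), each = 6),
    condition = rep(rep(c("JH", "JV"), each = 3), 3),
    replicate = rep(1:3, 6),
    fpkm = abs(stats::rnorm(18, 50, 10))
  )
  net <- build_coexpression_network("q", ex, k = 2L)
  expect_s3_class(autoplot(net), "ggplot")
})
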