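# a 20-nt miRNA makes the scored region equal the whole duplex, so the
# ungapped site is exactly 20 nt
mk_mirna <- function(base_at = integer(0), base = "G") {
  v <- rep("A", 20)
  v[base_at] <- base
  paste(v, collapse = "")
}

# site with selected miRNA positions mutated to a given target base
mk_site <- function(mirna, change_at = integer(0), to = "U") {
  svec <- strsplit(rev_comp(mirna), "")[[1]]
  S <- length(svec)
  svec[S - change_at + 1L] <- to
  paste(svec, collapse = "")
}

test_that("a perfect complement scores zero and is called cleavage", {
  m <- "UGACAGAAGAGAGUGAGCAC"
  dx <- score_duplex(m, rev_comp(m))
  expect_equal(dx$expectation, 0)
  expect_true(all(dx$states == "match"))
  expect_equal(classify_mode(dx), "cleavage")
})

test_that("wobble penalties are 0.5 outside and 1.0 inside the core", {
  m15 <- mk_mirna(15, "G")
  dx15 <- score_duplex(m15, mk_site(m15, 15, "U"))
  expect_equal(dx15$expectation, 0.5)
  expect_equal(dx15$states[15], "wobble")

  m5 <- mk_mirna(5, "G")
  dx5 <- score_duplex(m5, mk_site(m5, 5, "U"))
  expect_equal(dx5$expectation, 1.0)
})

test_that("a central mismatch costs 2 and flips the mode", {
  m <- mk_mirna()
  dx <- score_duplex(m, mk_site(m, 10, "C")) # A opposite C
  expect_equal(dx$expectation, 2.0)
  expect_equal(dx$states[10], "mismatch")
  expect_equal(classify_mode(dx), "translational_inhibition")
})

test_that("wobbles and edge mismatches do not trigger inhibition", {
  mw <- mk_mirna(10, "G")
  dxw <- score_duplex(mw, mk_site(mw, 10, "U"))
  expect_equal(dxw$states[10], "wobble")
  expect_equal(classify_mode(dxw), "cleavage")

  m <- mk_mirna()
  dx <- score_duplex(m, mk_site(m, c(1, 20), "C"))
  expect_equal(dx$expectation, 2.0) # 1 + 1, both outside the core
  expect_equal(classify_mode(dx), "cleavage")
})

test_that("score_duplex equals the alignment-DP oracle, gaps included", {
  withr::with_seed(31, {
    for (i in 1:40) {
      L <- sample(15:20, 1)
      m <- random_seq(L)
      U <- min(20L, L)
      S <- U + sample(-1:1, 1)
      site <- random_seq(S)
      dx <- score_duplex(m, site)
      expect_equal(
        dx$expectation, oracle_duplex_expectation(m, site),
        info = paste(m, site)
      )
    }
  })
})

test_that("the vectorized scanner agrees with score_duplex on every window", {
  withr::with_seed(32, {
    m <- random_seq(18)
    tx <- random_seq(70)
    sc <- mirframe:::scan_sites(m, tx, duplex_scheme())
    for (r in seq_len(nrow(sc))) {
      dx <- score_duplex(m, substr(tx, sc$site_start[r], sc$site_end[r]))
      expect_equal(sc$expectation[r], dx$expectation)
    }
  })
})

test_that("planted perfect sites are recovered at expectation zero", {
  withr::with_seed(33, {
    m <- random_seq(21)
    site <- rev_comp(m)
    tx <- seq_tbl(
      hit = paste0(random_seq(80), site, random_seq(80)),
      decoy = random_seq(180)
    )
    hits <- predict_targets(
      tibble::tibble(family = "miR-x", sequence = m), tx
    )
    expect_gte(nrow(hits), 1L)
    expect_equal(hits$expectation[1], 0)
    expect_equal(hits$transcript_id[1], "hit")
    expect_equal(hits$mode[1], "cleavage")
  })
})

test_that("sites beyond the expectation threshold are excluded", {
  # engineered 3.5: wobble at 15 (0.5) + mismatch at 1 (1.0) + mismatch
  # in the core at 10 (2.0)
  m <- mk_mirna(c(10, 15), "G")
  svec <- strsplit(rev_comp(m), "")[[1]]
  svec[20 - 15 + 1L] <- "U" # G:U wobble at 15
  svec[20 - 10 + 1L] <- "A" # G:A mismatch at 10
  svec[20 - 1 + 1L] <- "C" # A:C mismatch at 1
  site <- paste(svec, collapse = "")
  expect_equal(score_duplex(m, site)$expectation, 3.5)
  tx <- seq_tbl(t1 = site)
  hits <- predict_targets(
    tibble::tibble(family = "miR-x", sequence = m), tx,
    max_expectation = 3
  )
  expect_equal(nrow(hits), 0L)
})

test_that("per-miRNA output is truncated to the top_n best sites", {
  withr::with_seed(34, {
    m <- random_seq(20)
    site <- rev_comp(m)
    spacer <- function() random_seq(30, c("A", "C"))
    tx <- seq_tbl(t1 = paste0(
      spacer(), site, spacer(), site, spacer(), site, spacer(), site,
      spacer(), site, spacer()
    ))
    all_hits <- predict_targets(
      tibble::tibble(family = "miR-x", sequence = m), tx
    )
    perfect <- dplyr::filter(all_hits, expectation == 0)
    expect_equal(nrow(perfect), 5L)
    top3 <- predict_targets(
      tibble::tibble(family = "miR-x", sequence = m), tx,
      top_n = 3L
    )
    expect_equal(nrow(top3), 3L)
    # deterministic tie-break: ascending site_start among equal scores
    expect_equal(top3$site_start, sort(top3$site_start))
  })
})

test_that("prediction output is stable under input permutation", {
  withr::with_seed(35, {
    m <- random_seq(20)
    tx <- seq_tbl(
      a = paste0(random_seq(40), rev_comp(m), random_seq(40)),
      b = random_seq(100),
      c = paste0(rev_comp(m), random_seq(60))
    )
    mir <- tibble::tibble(family = "miR-x", sequence = m)
    h1 <- predict_targets(mir, tx)
    h2 <- predict_targets(mir, tx[c(3, 1, 2), ])
    expect_equal(h1, h2)
  })
})

test_that("site flanks extend 17/13 and clip at transcript bounds", {
  tx <- strrep("A", 200)
  fl <- site_flanks(tx, 100L, 121L)
  expect_equal(fl$start, 83L)
  expect_equal(fl$end, 134L)
  expect_equal(nchar(fl$sequence), 52L)
  edge <- site_flanks(tx, 3L, 23L)
  expect_equal(edge$start, 1L)
  # the flanked region always contains the site
  expect_gte(100L, fl$start)
  expect_lte(121L, fl$end)
})
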