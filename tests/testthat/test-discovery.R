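mk_mature <- function(s) tibble::tibble(id = "miR-9001", sequence = s)

test_that("an exact planted mature copy is found once with zero mismatches", {
  withr::with_seed(21, {
    mature <- random_seq(21)
    tx <- seq_tbl(t1 = paste0(
      random_seq(200, c("A", "C")), mature, random_seq(200, c("A", "C"))
    ))
    hits <- find_mature_matches(tx, mk_mature(mature))
    fwd <- dplyr::filter(hits, strand == "+")
    expect_equal(nrow(fwd), 1L)
    expect_equal(fwd$start, 201L)
    expect_equal(fwd$end, 221L)
    expect_equal(fwd$mismatches, 0L)
    expect_equal(fwd$family, "miR-9001")
  })
})

test_that("windows without shared similarity yield no matches", {
  tx <- seq_tbl(t1 = strrep("A", 300))
  hits <- find_mature_matches(tx, mk_mature(strrep("G", 21)))
  expect_equal(nrow(hits), 0L)
})

test_that("plants beyond the mismatch tier are dropped", {
  withr::with_seed(22, {
    mature <- random_seq(21)
    mvec <- strsplit(mature, "")[[1]]
    flip <- c(A = "C", C = "A", G = "A", U = "C")
    mvec[c(2, 6, 10, 14, 18)] <- flip[mvec[c(2, 6, 10, 14, 18)]]
    tx <- seq_tbl(t1 = paste0(
      strrep("A", 150), paste(mvec, collapse = ""), strrep("A", 150)
    ))
    hits <- find_mature_matches(tx, mk_mature(mature), max_mismatches = 4L)
    expect_equal(nrow(hits), 0L)
    # retained at a looser tier, labelled putative
    hits5 <- find_mature_matches(
      tx, mk_mature(mature),
      max_mismatches = 5L, evalue_cutoff = 1
    )
    expect_true(all(hits5$mismatches == 5L))
    expect_true(all(startsWith(hits5$family, "miR-f")))
  })
})

test_that("lowering the e-value cutoff never adds matches", {
  withr::with_seed(23, {
    mature <- random_seq(21)
    tx <- seq_tbl(
      t1 = paste0(random_seq(120), mature, random_seq(120)),
      t2 = random_seq(400)
    )
    loose <- find_mature_matches(tx, mk_mature(mature), evalue_cutoff = 1)
    strict <- find_mature_matches(tx, mk_mature(mature), evalue_cutoff = 1e-5)
    key <- function(x) paste(x$transcript_id, x$start, x$strand)
    expect_true(all(key(strict) %in% key(loose)))
    expect_lte(nrow(strict), nrow(loose))
  })
})

test_that("precursor windows use clipped flank arithmetic", {
  tx <- seq_tbl(t1 = strrep("A", 400))
  matches <- tibble::tibble(
    transcript_id = "t1", mature_id = "m", family = "miR-1",
    start = c(201L, 5L), end = c(221L, 25L), strand = "+",
    mismatches = 0L, evalue = 0, mature_length = 21L
  )
  pre <- extract_precursors(tx, matches, flank = 120L)
  expect_equal(pre$window_start, c(81L, 1L))
  expect_equal(pre$window_end, c(341L, 145L))
  expect_equal(pre$mature_start, c(121L, 5L))
  expect_equal(nchar(pre$window_sequence[1]), 261L)
  # mature span sits inside the window
  expect_true(all(pre$mature_end <= nchar(pre$window_sequence)))
})

test_that("criteria flags respond to threshold and geometry changes", {
  withr::with_seed(24, {
    mature <- "GCAGCCGUCAGGCAUGCAGC"
    tx <- seq_tbl(t1 = paste0(
      random_seq(150, c("A", "C")),
      mature, "AAACAA", rev_comp(mature),
      random_seq(150, c("A", "C"))
    ))
    res <- identify_mirnas(tx, mk_mature(mature))
    cand <- dplyr::filter(res$candidates, strand == "+", mismatches == 0)
    expect_true(all(cand$accepted))
    expect_true(all(
      cand$accepted == (cand$is_candidate & cand$has_hairpin &
        cand$mature_in_one_arm & cand$duplex_mismatch_ok &
        cand$no_loop_or_break & cand$mfe_ok)
    ))
    # an unreachable MFE bound flips only mfe_ok
    strict <- identify_mirnas(tx, mk_mature(mature), mfe_threshold = -200)
    cand2 <- dplyr::filter(strict$candidates, strand == "+", mismatches == 0)
    expect_false(any(cand2$mfe_ok))
    expect_false(any(cand2$accepted))
    expect_true(all(cand2$has_hairpin))
  })
})

test_that("a mature spanning the terminal loop violates the loop criterion", {
  stem <- "GGCCGCGGCCGCGGC"
  window <- paste0(
    strrep("A", 20), stem, "AAAA", rev_comp(stem), strrep("A", 20)
  )
  f <- fold_rna(window)
  # mature covering the last 9 stem bases, the loop and 8 star bases
  flags <- mirframe:::criterion_flags(f, 27L, 47L)
  expect_false(flags$no_loop_or_break)
  expect_false(flags$mature_in_one_arm)
})

test_that("inventories collapse isoforms into families", {
  cand <- tibble::tibble(
    family = c("miR-156a", "miR-156b", "miR-5658"),
    accepted = TRUE
  )
  inv <- build_inventory(cand, "JH")
  expect_equal(inv$family, c("miR-156", "miR-5658"))
  expect_equal(inv$n_candidates, c(2L, 1L))
  expect_equal(unique(inv$condition), "JH")
  empty <- build_inventory(tibble::tibble(family = character()), "JV")
  expect_equal(nrow(empty), 0L)
})
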