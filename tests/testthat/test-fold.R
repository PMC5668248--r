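test_that("a sequence with no complementarity stays unpaired at zero energy", {
  f <- fold_rna("AAAAAAAAAA")
  expect_equal(f$mfe, 0)
  expect_equal(f$n_pairs, 0L)
  expect_equal(f$structure, strrep(".", 10))
  expect_equal(nchar(f$structure), nchar(f$sequence))
})

test_that("a perfect stem folds to the full hairpin at the enumeration MFE", {
  f <- fold_rna("GGGGGAAAACCCCC")
  expect_equal(f$structure, "(((((....)))))")
  expect_equal(f$n_pairs, 5L)
  orc <- oracle_fold_mfe("GGGGGAAAACCCCC")
  expect_equal(f$mfe, orc$mfe)
  expect_equal(f$n_pairs, orc$n_pairs)
})

test_that("DP energies match exhaustive enumeration on short sequences", {
  withr::with_seed(42, {
    for (i in 1:80) {
      n <- sample(5:12, 1)
      letters <- if (i %% 10 == 0) c("A", "C", "G", "U", "N") else c("A", "C", "G", "U")
      s <- random_seq(n, letters)
      f <- fold_rna(s)
      orc <- oracle_fold_mfe(s)
      expect_equal(f$mfe, orc$mfe, info = s)
      expect_equal(f$n_pairs, orc$n_pairs, info = s)
    }
  })
})

test_that("fold output metadata is structurally consistent", {
  withr::with_seed(9, {
    for (i in 1:20) {
      s <- random_seq(sample(10:60, 1))
      f <- fold_rna(s)
      expect_lte(f$mfe, 0)
      expect_equal(nchar(f$structure), nchar(s))
      paired <- which(f$pair_table > 0L)
      expect_equal(f$pair_table[f$pair_table[paired]], paired)
      expect_equal(sum(f$pair_table > 0L) %/% 2L, f$n_pairs)
      # dot-bracket agrees with the pair table
      expect_equal(
        mirframe:::pair_table_from_dotbracket(f$structure), f$pair_table
      )
    }
  })
})

test_that("closing a sequence with a complementary pair never raises the MFE", {
  withr::with_seed(11, {
    for (i in 1:15) {
      s <- random_seq(sample(8:25, 1))
      expect_lte(fold_rna(paste0("G", s, "C"))$mfe, fold_rna(s)$mfe)
    }
  })
})

test_that("arm classification reads the hairpin geometry", {
  f <- fold_rna("GGGGGAAAACCCCC")
  expect_equal(arm_of(f, 2L), "five_prime_arm")
  expect_equal(arm_of(f, 7L), "loop")
  expect_equal(arm_of(f, 12L), "three_prime_arm")
  un <- fold_rna("AAAAAAAAAA")
  expect_equal(unique(arm_of(un)), "unpaired_tail")
})

test_that("duplex mismatches count unpaired and mispaired mature bases", {
  mature <- "GCAGCCGUCAGGCAUGCAGC"
  f <- fold_rna(paste0(mature, "AAACAA", rev_comp(mature)))
  expect_equal(duplex_mismatches(f, 1L, nchar(mature)), 0L)
  # seven engineered single mismatches (the fail_mismatches construction)
  ins <- mirframe:::mirror_stem_insert(
    "AGGACCAGGACCAGGACCAGG", seq(1L, 19L, by = 3L)
  )
  f2 <- fold_rna(ins)
  expect_equal(duplex_mismatches(f2, 7L, 27L), 7L)
  # a mature span outside any arm is a criterion-3 violation
  expect_error(duplex_mismatches(f, 1L, nchar(f$sequence)), "single hairpin arm")
})

test_that("a command backend honouring the RNAfold stdout contract plugs in", {
  f <- fold_rna("GGGGGAAAACCCCC", backend = "RNAfold --noPS")
  expect_equal(nchar(f$structure), 14L)
  expect_lte(f$mfe, 0)
  expect_equal(length(f$pair_table), 14L)
  # function backends satisfy the same contract
  fun <- function(s) list(structure = strrep(".", nchar(s)), mfe = 0)
  f2 <- fold_rna("ACGUACGUAC", backend = fun)
  expect_equal(f2$n_pairs, 0L)
})
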