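# Seeded synthetic inputs for every pipeline stage: transcriptomes with
# planted miRNA precursors (per compliance profile) and target sites,
# layered GO DAGs with annotations, and replicate FPKM tables with planted
# correlated gene groups. Truth tables are first-class outputs so tests
# can assert recovery without re-deriving ground truth.

#' Simulation configuration
#'
#' The seed fully determines all generator outputs. Compliance profiles
#' for planted precursors: `all_pass` (satisfies all six criteria),
#' `fail_mfe` (A/U-only stem too weak for the MFE bound), `fail_arm`
#' (mature planted in an unpaired tail outside the hairpin),
#' `fail_mismatches` (seven single-base mismatches against the star arm),
#' `fail_loop` (one 3-base unpaired run inside the mature pairing block).
#'
#' @param seed Integer seed.
#' @param n_transcripts Background transcripts per condition.
#' @param transcript_length Length range (min, max) of background
#'   transcripts.
#' @param precursor_profiles Character vector of compliance profiles to
#'   plant (one transcript each).
#' @param n_target_sites Perfect miRNA target sites to plant.
#' @param n_mirnas Mature reference sequences to emit.
#' @param mature_length Mature miRNA length.
#' @param n_genes Genes in the expression table.
#' @param n_replicates Replicates per condition (>= 3).
#' @param conditions Two condition labels.
#' @param coexpr_groups Number of planted co-expressed groups.
#' @param group_size Genes per planted group.
#' @param planted_pcc Target pairwise correlation within groups.
#' @param fpkm_sigma Log-normal noise sd on log-FPKM.
#' @param n_go_terms Total GO terms in the synthetic DAG.
#' @param dag_depth Layers below the root (>= 1).
#' @param annotations_per_transcript Mean direct GO annotations per
#'   transcript.
#' @return A validated `mir_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 20L,
                              transcript_length = c(400L, 900L),
                              precursor_profiles = c(
                                "all_pass", "all_pass", "all_pass",
                                "fail_mfe", "fail_arm",
                                "fail_mismatches", "fail_loop"
                              ),
                              n_target_sites = 3L,
                              n_mirnas = 3L,
                              mature_length = 21L,
                              n_genes = 40L,
                              n_replicates = 5L,
                              conditions = c("JH", "JV"),
                              coexpr_groups = 2L,
                              group_size = 5L,
                              planted_pcc = 0.95,
                              fpkm_sigma = 0.3,
                              n_go_terms = 25L,
                              dag_depth = 3L,
                              annotations_per_transcript = 3) {
  profiles_ok <- c(
    "all_pass", "fail_mfe", "fail_arm", "fail_mismatches", "fail_loop"
  )
  if (!all(precursor_profiles %in% profiles_ok)) {
    abort(paste0(
      "unknown compliance profile(s): ",
      paste(setdiff(precursor_profiles, profiles_ok), collapse = ", ")
    ))
  }
  stopifnot(
    length(conditions) == 2L, n_replicates >= 3L,
    planted_pcc > 0, planted_pcc < 1, fpkm_sigma >= 0,
    dag_depth >= 1L, length(transcript_length) == 2L,
    transcript_length[1] >= 300L, mature_length >= 18L,
    mature_length <= 26L
  )
  structure(
    list(
      seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
      transcript_length = as.integer(transcript_length),
      precursor_profiles = precursor_profiles,
      n_target_sites = as.integer(n_target_sites),
      n_mirnas = as.integer(n_mirnas),
      mature_length = as.integer(mature_length),
      n_genes = as.integer(n_genes),
      n_replicates = as.integer(n_replicates),
      conditions = conditions,
      coexpr_groups = as.integer(coexpr_groups),
      group_size = as.integer(group_size),
      planted_pcc = planted_pcc, fpkm_sigma = fpkm_sigma,
      n_go_terms = as.integer(n_go_terms),
      dag_depth = as.integer(dag_depth),
      annotations_per_transcript = annotations_per_transcript
    ),
    class = "mir_sim_config"
  )
}

# --- planted precursor construction ---------------------------------------

# star arm mirroring a mature whose mismatch positions are A: complement
# (G<->C) everywhere except the mismatch positions, which stay A so the
# opposition is A:A (unpairable in a U-free window); plus a non-palindromic
# G/C closing stem
mirror_stem_insert <- function(mature, mm_pos) {
  m <- strsplit(mature, "")[[1]]
  L <- length(m)
  star <- vapply(seq_len(L), function(q) {
    p <- L + 1L - q
    if (p %in% mm_pos) "A" else chartr("GC", "CG", m[p])
  }, character(1))
  extra <- "GGCGGC"
  paste0(extra, mature, "AAAAAA", paste(star, collapse = ""), "GCCGCC")
}

# hairpin insert + expected criterion flags for one compliance profile;
# returns list(insert, mature, mature_offset (within insert), expected)
build_plant <- function(profile, mature_length) {
  sub_safe <- c(A = "C", C = "A", G = "A", U = "C") # never re-pairs
  expected <- c(
    is_candidate = TRUE, has_hairpin = TRUE, mature_in_one_arm = TRUE,
    duplex_mismatch_ok = TRUE, no_loop_or_break = TRUE, mfe_ok = TRUE
  )
  if (profile == "all_pass") {
    # G/C-rich mature so the 21-pair stem clears the -20 kcal/mol bound
    # comfortably whatever the surrounding background folds into
    repeat {
      mature <- random_rna(1, mature_length,
        letters = c("A", "C", "G", "U"), prob = c(0.2, 0.3, 0.3, 0.2)
      )
      if (stringr::str_count(mature, "[GC]") >= 12L) break
    }
    insert <- paste0(mature, "AAACAA", rev_comp(mature))
    offset <- 0L
  } else if (profile == "fail_mfe") {
    # A/U-only stem: every possible stack is the weak AU/AU term, so the
    # window MFE cannot reach -20 whatever the background folds into
    mature <- random_rna(1, mature_length, letters = c("A", "U"))
    insert <- paste0(mature, "CCCCCC", rev_comp(mature))
    offset <- 0L
    expected["mfe_ok"] <- FALSE
  } else if (profile == "fail_arm") {
    # hairpin from an inert C/G stem; the mature sits in a single-stranded
    # tail 30 nt downstream, so it is in no arm but touches no loop either
    mature <- random_rna(1, mature_length, letters = c("A", "C"))
    hairpin <- paste0(
      strrep("C", 14), "AAAA", strrep("G", 14)
    )
    insert <- paste0(hairpin, strrep("A", 30), mature)
    offset <- nchar(hairpin) + 30L
    expected["mature_in_one_arm"] <- FALSE
  } else if (profile == "fail_mismatches") {
    # seven isolated single-base mismatches (every third position) facing
    # A:A oppositions in a U-free window, so the mismatched bases cannot
    # pair with anything; GG/CC helix blocks alternate to forbid register
    # slippage (a shifted register would oppose G to G and C to C)
    # mismatches at 1, 4, ..., 19 keep the loop-adjacent mature end paired
    mm_pos <- seq(1L, 19L, by = 3L)
    mature <- "AGGACCAGGACCAGGACCAGG"
    insert <- mirror_stem_insert(mature, mm_pos)
    offset <- 6L # length of the extra closing stem
    expected["duplex_mismatch_ok"] <- FALSE
  } else { # fail_loop
    # one 3-base A:A run splitting the mature pairing block; same U-free
    # anti-slippage construction, mismatches (3) stay below seven
    mm_pos <- 10:12
    mature <- paste0("GGCCGCGGC", "AAA", "CCGGCGCCG")
    insert <- mirror_stem_insert(mature, mm_pos)
    offset <- 6L
    expected["no_loop_or_break"] <- FALSE
  }
  list(
    insert = insert, mature = mature, mature_offset = offset,
    expected = expected
  )
}

#' Generate a synthetic transcriptome with planted precursors and sites
#'
#' Background transcripts are uniform over \{A, C, G, U\}; each configured
#' compliance profile is planted into its own transcript (the profile's
#' construction keeps the surrounding window inert where the profile
#' depends on it), and `n_target_sites` perfect complements of the first
#' mature sequences are planted into background transcripts.
#'
#' @param config A `mir_sim_config`.
#' @return List with `transcripts` (tibble `id`, `sequence`), `mature`
#'   (tibble `id`, `sequence`), `truth_precursors` (planted coordinates,
#'   profile and the six expected criterion flags) and `truth_sites`
#'   (planted target-site coordinates).
#' @export
make_transcriptome <- function(config) {
  stopifnot(inherits(config, "mir_sim_config"))
  withr::with_seed(config$seed, {
    lens <- sample(
      seq(config$transcript_length[1], config$transcript_length[2]),
      config$n_transcripts,
      replace = TRUE
    )
    transcripts <- tibble::tibble(
      id = sprintf("tx%03d", seq_len(config$n_transcripts)),
      sequence = random_rna(config$n_transcripts, lens)
    )
    mature_ref <- tibble::tibble(
      id = sprintf("miR-90%02d", seq_len(config$n_mirnas)),
      sequence = random_rna(
        config$n_mirnas, config$mature_length,
        prob = c(0.2, 0.3, 0.3, 0.2)
      )
    )
    # plant precursors into dedicated transcripts appended to the set;
    # each construction is verified against its intended profile (the
    # folding model can rearrange self-similar stems) and redrawn, still
    # under the seed, until the planted window shows exactly the intended
    # criterion pattern
    truth_pre <- list()
    for (i in seq_along(config$precursor_profiles)) {
      profile <- config$precursor_profiles[i]
      plant <- NULL
      for (try in 1:50) {
        cand <- build_plant(profile, config$mature_length)
        pad_letters <- if (profile == "all_pass") {
          c("A", "C", "G", "U")
        } else {
          # inert padding for profiles whose verdict depends on the
          # window staying structure-free
          c("A", "C")
        }
        cand$pad5 <- random_rna(1, 150, letters = pad_letters)
        cand$pad3 <- random_rna(1, 150, letters = pad_letters)
        m_start <- nchar(cand$pad5) + cand$mature_offset + 1L
        m_end <- m_start + nchar(cand$mature) - 1L
        seq <- paste0(cand$pad5, cand$insert, cand$pad3)
        ws <- max(1L, m_start - 120L)
        window <- substr(seq, ws, min(nchar(seq), m_end + 120L))
        flags <- criterion_flags(
          fold_rna(window), m_start - ws + 1L, m_end - ws + 1L
        )
        got <- unlist(flags[names(cand$expected)])
        if (identical(unname(got), unname(cand$expected))) {
          plant <- cand
          break
        }
      }
      if (is.null(plant)) {
        abort(paste0("could not engineer a compliant ", profile, " plant"))
      }
      id <- sprintf("plant%02d_%s", i, profile)
      seq <- paste0(plant$pad5, plant$insert, plant$pad3)
      m_start <- nchar(plant$pad5) + plant$mature_offset + 1L
      transcripts <- dplyr::bind_rows(
        transcripts,
        tibble::tibble(id = id, sequence = seq)
      )
      mature_ref <- dplyr::bind_rows(
        mature_ref,
        tibble::tibble(
          id = sprintf("miR-91%02d", i), sequence = plant$mature
        )
      )
      truth_pre[[i]] <- tibble::tibble(
        transcript_id = id, mature_id = sprintf("miR-91%02d", i),
        profile = profile, mature_start = m_start,
        mature_end = m_start + nchar(plant$mature) - 1L,
        !!!as.list(plant$expected)
      )
    }
    # plant perfect target sites for the first mature reference sequences
    truth_sites <- list()
    n_sites <- min(config$n_target_sites, config$n_mirnas, config$n_transcripts)
    for (i in seq_len(n_sites)) {
      site <- rev_comp(mature_ref$sequence[i])
      tx <- i # one site per transcript, deterministic placement
      tseq <- transcripts$sequence[tx]
      pos <- 101L
      transcripts$sequence[tx] <- paste0(
        substr(tseq, 1, pos - 1L), site,
        substr(tseq, pos, nchar(tseq))
      )
      truth_sites[[i]] <- tibble::tibble(
        mirna_id = mature_ref$id[i], transcript_id = transcripts$id[tx],
        site_start = pos, site_end = pos + nchar(site) - 1L
      )
    }
    list(
      transcripts = transcripts,
      mature = mature_ref,
      truth_precursors = dplyr::bind_rows(truth_pre),
      truth_sites = dplyr::bind_rows(truth_sites)
    )
  })
}

#' Generate a synthetic replicate FPKM table with planted correlation
#'
#' Gene log-FPKM is `mu_g + b z_{c,r} + sigma eps` with a latent factor z
#' shared within each planted group (per condition and replicate) and
#' loading `b = sigma * sqrt(rho / (1 - rho))`, so the within-group
#' log-scale pairwise correlation is the configured `planted_pcc`. With
#' `fpkm_sigma = 0` a fixed positive loading is used and within-group
#' FPKM correlation is exactly 1.
#'
#' @param config A `mir_sim_config`.
#' @return List with `expression` (long tibble) and `truth_groups`
#'   (tibble `gene`, `group`).
#' @export
make_expression <- function(config) {
  stopifnot(inherits(config, "mir_sim_config"))
  withr::with_seed(config$seed + 1L, {
    genes <- sprintf("g%03d", seq_len(config$n_genes))
    mu <- stats::runif(config$n_genes, log(20), log(500))
    group_of <- rep(NA_integer_, config$n_genes)
    idx <- seq_len(min(
      config$coexpr_groups * config$group_size, config$n_genes
    ))
    group_of[idx] <- rep(
      seq_len(config$coexpr_groups),
      each = config$group_size
    )[seq_along(idx)]
    sigma <- config$fpkm_sigma
    b <- if (sigma == 0) 0.3 else {
      sigma * sqrt(config$planted_pcc / (1 - config$planted_pcc))
    }
    rows <- list()
    for (cond in config$conditions) {
      z <- matrix(
        stats::rnorm(config$coexpr_groups * config$n_replicates),
        config$coexpr_groups, config$n_replicates
      )
      for (g in seq_len(config$n_genes)) {
        latent <- if (!is.na(group_of[g])) z[group_of[g], ] else 0
        eps <- stats::rnorm(config$n_replicates, 0, sigma)
        fpkm <- exp(mu[g] + b * latent + eps)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          transcript_id = genes[g], condition = cond,
          replicate = seq_len(config$n_replicates), fpkm = fpkm
        )
      }
    }
    list(
      expression = as_expression_table(dplyr::bind_rows(rows)),
      truth_groups = tibble::tibble(gene = genes, group = group_of)
    )
  })
}

#' Generate a synthetic layered GO DAG with annotations
#'
#' Terms are arranged in layers below a single root; each term in layer
#' d >= 1 gets one or two parents in layer d - 1 (acyclic by
#' construction). Annotations are drawn over the deepest-layer terms.
#'
#' @param config A `mir_sim_config`.
#' @param transcripts Transcript ids to annotate (default: gene ids
#'   matching [make_expression()]).
#' @return List with `dag` (a `mir_go_dag`), `annotations` (tibble) and
#'   `truth_counts` (tibble `go_term`, `gp`: direct annotation counts).
#' @export
make_go <- function(config, transcripts = NULL) {
  stopifnot(inherits(config, "mir_sim_config"))
  withr::with_seed(config$seed + 2L, {
    transcripts <- transcripts %||% sprintf("g%03d", seq_len(config$n_genes))
    n <- max(config$n_go_terms, config$dag_depth + 1L)
    # distribute terms over layers: 1 root, remainder spread below
    layer_sizes <- c(1L, rep(0L, config$dag_depth))
    remaining <- n - 1L
    for (d in seq_len(config$dag_depth)) {
      take <- if (d == config$dag_depth) {
        remaining
      } else {
        max(1L, round(remaining / (config$dag_depth - d + 1)))
      }
      layer_sizes[d + 1L] <- take
      remaining <- remaining - take
    }
    ids <- sprintf("GO:%07d", seq_len(n))
    layer <- rep(seq_along(layer_sizes) - 1L, layer_sizes)
    terms <- tibble::tibble(
      id = ids,
      name = paste0("synthetic term ", seq_len(n)),
      namespace = "BP"
    )
    edges <- list()
    for (t in which(layer > 0L)) {
      parents_pool <- ids[layer == layer[t] - 1L]
      n_par <- min(length(parents_pool), sample(1:2, 1))
      for (p in sample(parents_pool, n_par)) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          child = ids[t], parent = p
        )
      }
    }
    dag <- new_go_dag(terms, dplyr::distinct(dplyr::bind_rows(edges)))
    leaves <- ids[layer == max(layer)]
    ann <- list()
    for (tx in transcripts) {
      k <- max(1L, stats::rpois(1, config$annotations_per_transcript))
      ann[[length(ann) + 1L]] <- tibble::tibble(
        transcript_id = tx,
        go_term = sample(leaves, min(k, length(leaves)))
      )
    }
    annotations <- dplyr::distinct(dplyr::bind_rows(ann))
    truth <- dplyr::count(annotations, .data$go_term, name = "gp")
    list(dag = dag, annotations = annotations, truth_counts = truth)
  })
}
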