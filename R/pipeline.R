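# End-to-end driver: the six analysis stages in workflow order
# (annotation/input validation, miRNA identification, target prediction,
# GO node-score network, degree + correlation analysis, co-expression
# network), each writing its outputs under the run directory, plus a
# manifest with the config, seed and output hashes.

#' Run the full six-stage pipeline
#'
#' Inputs can be given as files (`transcripts`, `mature` FASTA;
#' `expression`, `annotations` TSV; `obo`) or as in-memory objects; when
#' `simulate = TRUE` all inputs are generated from the synthetic-data
#' module under `config$seed`. Each stage writes TSV/graph outputs into
#' `out_dir`; a failure stops with the failing stage named, keeping
#' earlier outputs.
#'
#' @param config A `mir_run_config`.
#' @param out_dir Output directory (created if missing).
#' @param transcripts,mature Sequence tibbles or FASTA paths.
#' @param expression Expression tibble or TSV path.
#' @param annotations GO annotation tibble or TSV path.
#' @param dag A `mir_go_dag` or OBO path.
#' @param conditions Two condition labels: the transcript set is
#'   profiled once per condition against its expression values.
#' @param simulate Generate all inputs synthetically.
#' @param sim_config `mir_sim_config` used when `simulate = TRUE`
#'   (default derived from `config$seed`).
#' @return A `mir_run` list with every stage result and the manifest.
#' @export
run_all <- function(config = run_config(), out_dir,
                    transcripts = NULL, mature = NULL, expression = NULL,
                    annotations = NULL, dag = NULL,
                    conditions = c("JH", "JV"),
                    simulate = FALSE, sim_config = NULL) {
  stopifnot(inherits(config, "mir_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # stage 1: input assembly / validation
  inputs <- stage("data_annotation", {
    if (simulate) {
      sim <- sim_config %||% simulation_config(seed = config$seed)
      tx <- make_transcriptome(sim)
      ex <- make_expression(sim)
      go <- make_go(sim)
      list(
        transcripts = tx$transcripts, mature = tx$mature,
        expression = ex$expression, annotations = go$annotations,
        dag = go$dag, truth = list(
          precursors = tx$truth_precursors, sites = tx$truth_sites,
          groups = ex$truth_groups, counts = go$truth_counts
        )
      )
    } else {
      resolve <- function(x, reader, what) {
        if (is.null(x)) abort(paste0("missing input: ", what))
        if (is.character(x) && length(x) == 1L) {
          if (!file.exists(x)) abort(paste0("missing input file: ", x))
          return(reader(x))
        }
        x
      }
      list(
        transcripts = resolve(transcripts, read_fasta, "transcripts"),
        mature = resolve(
          mature, function(p) read_fasta(p, kind = "mature_mirna"), "mature"
        ),
        expression = resolve(expression, read_expression, "expression"),
        dag = resolve(dag, read_obo_lite, "dag"),
        annotations = if (is.character(annotations)) {
          read_go_annotations(annotations, if (is.character(dag)) read_obo_lite(dag) else dag)
        } else {
          annotations %||% abort("missing input: annotations")
        },
        truth = NULL
      )
    }
  })
  if (config$accessibility == FALSE && config$max_unpair_energy != 25) {
    warn("max_unpair_energy is ignored while the accessibility filter is off")
  }
  readr::write_tsv(inputs$transcripts["id"], file.path(out_dir, "stage1_inputs.tsv"))

  # stage 2: miRNA identification
  ident <- stage("mirna_identification", {
    identify_mirnas(
      inputs$transcripts, inputs$mature,
      condition = conditions[1],
      max_mismatches = config$max_mismatches,
      evalue_cutoff = config$evalue_cutoff,
      flank = config$flank, mfe_threshold = config$mfe_threshold,
      max_duplex_mismatches = config$max_duplex_mismatches,
      min_stem_pairs = config$min_stem_pairs
    )
  })
  readr::write_tsv(
    dplyr::select(ident$candidates, -dplyr::any_of(c("fold", "states"))),
    file.path(out_dir, "stage2_mirna_candidates.tsv")
  )
  readr::write_tsv(ident$inventory, file.path(out_dir, "stage2_inventory.tsv"))

  # stage 3: target prediction with the accepted families
  targets <- stage("target_prediction", {
    accepted <- dplyr::filter(ident$candidates, .data$accepted)
    mirnas <- dplyr::distinct(
      tibble::tibble(
        family = accepted$family,
        sequence = inputs$mature$sequence[
          match(accepted$mature_id, inputs$mature$id)
        ]
      )
    )
    scheme <- duplex_scheme(core_double = config$core_double)
    predict_targets(
      mirnas, inputs$transcripts,
      max_expectation = config$max_expectation,
      top_n = config$top_n, scheme = scheme
    )
  })
  readr::write_tsv(
    dplyr::select(targets, -dplyr::any_of("states")),
    file.path(out_dir, "stage3_targets.tsv")
  )

  # stage 4: GO node-score network over the targeted transcripts
  go_net <- stage("go_network", {
    scores <- score_transcripts(
      inputs$dag, inputs$annotations,
      alpha = config$alpha, namespace = config$go_namespace
    )
    clusters <- cluster_by_score(scores, inputs$annotations)
    filter_top_nodes(clusters, config$min_score)
  })
  readr::write_tsv(go_net$clusters, file.path(out_dir, "stage4_go_clusters.tsv"))

  # stage 5: bipartite network + degree and correlation analysis
  network <- stage("degree_correlation", {
    pairs <- dplyr::distinct(
      dplyr::transmute(
        targets,
        mirna = .data$mirna, target = .data$transcript_id
      )
    )
    bip <- if (nrow(pairs) > 0L) build_bipartite(pairs, conditions[1]) else NULL
    prof <- if (!is.null(bip)) degree_profile(bip) else NULL
    dc <- if (!is.null(bip) && igraph::ecount(bip$graph) > 0L) {
      degree_correlation(bip)
    } else {
      NULL
    }
    list(bipartite = bip, profile = prof, correlation = dc)
  })
  if (!is.null(network$bipartite)) {
    write_network(
      network$bipartite, file.path(out_dir, "stage5_bipartite.sif"),
      format = "sif"
    )
    readr::write_tsv(
      network$profile$degrees,
      file.path(out_dir, "stage5_degrees.tsv")
    )
  } else {
    writeLines(character(0), file.path(out_dir, "stage5_bipartite.sif"))
  }

  # stage 6: co-expression network around the most-targeted genes
  coexpr <- stage("coexpression", {
    genes <- unique(inputs$expression$transcript_id)
    queries <- head(genes, min(3L, length(genes)))
    build_coexpression_network(
      queries, inputs$expression, inputs$annotations,
      weights = config$weights, k = config$k
    )
  })
  write_network(
    coexpr, file.path(out_dir, "stage6_coexpression.tsv"),
    format = "tsv"
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirframe")),
    seed = config$seed,
    config = config[setdiff(names(config), character(0))],
    outputs = as.list(tools::md5sum(sort(
      setdiff(
        list.files(out_dir, full.names = TRUE),
        file.path(out_dir, "manifest.json")
      )
    )))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(structure(
    list(
      inputs = inputs, identification = ident, targets = targets,
      go_network = go_net, network = network, coexpression = coexpr,
      manifest = manifest, out_dir = out_dir
    ),
    class = "mir_run"
  ))
}
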