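# mirframe

Differential miRNA network analysis for transcriptome comparisons:
discover miRNA precursors by homology and hairpin validation, score
miRNA→mRNA targets, and profile the resulting regulation as bipartite,
GO node-score and co-expression networks.

## The problem

Comparing two conditions of the same tissue (the shipped example
contrasts healthy, `JH`, and virus-infected, `JV`, plant leaf
transcriptomes) at the level of miRNA regulation takes six coupled
steps, each with its own statistics:

1. **miRNA identification.** Mature reference sequences are matched
   against the transcriptome (100% identity for family assignment; up
   to 4 mismatches retained as putative candidates; occurrence e-value
   ≤ 1e−5). Each match's surrounding window must fold into a stem–loop
   that passes six criteria: candidate selection, a hairpin stem of
   ≥ 12 pairs, mature in one arm, fewer than 7 duplex mismatches
   against the opposite arm, no loop or break in the mature, and a
   minimum free energy ≤ −20 kcal/mol under the package's
   nearest-neighbour folding model (Watson–Crick + G:U stacking with
   flat loop penalties).
2. **Target prediction.** Duplex expectation scoring over the first 20
   miRNA positions (match 0, wobble 0.5, mismatch 1, gap 2; doubled in
   core positions 2–13; ≤ 1 gap), keeping sites with expectation ≤ 3,
   top 200 per miRNA. A mismatch at positions 9–11 calls translational
   inhibition, otherwise cleavage.
3. **Interaction matrix and bipartite networks.** `A[i,j] = 1` iff
   miRNA i targets transcript j, viewed as a directed bipartite graph;
   condition-unique and common-miRNA differential variants.
4. **GO node-score network.**
   `score(g) = Σ_{gα ∈ desc(g)} gp(gα)·α^dist(g,gα)` over the `is_a`
   descendant closure (α default 0.6); transcripts are clustered by
   score with shared-term inter-cluster edges.
5. **Degree and correlation analysis.** Degree distributions `p(k)`,
   the degree-assortativity coefficient r over symmetrized
   endpoint-degree pairs (star → −1, regular → undefined), and Pearson
   correlation of FPKM between conditions.
6. **Co-expression reconstruction.** Per candidate gene, a weighted
   combined score `0.4·abundance + 0.3·GO + 0.3·PCC` (components
   normalised to [0, 1]) and the top 20 neighbours per query gene form
   an undirected co-expression network.

A fully seeded synthetic-data module generates transcriptomes with
planted precursors (per-criterion compliance profiles), perfect target
sites, layered GO DAGs and replicate FPKM tables with planted
correlation, so the whole pipeline is testable without downloads.

## Worked example

The packaged fixture tables transcribe a published healthy/diseased
target comparison:

```r
library(mirframe)

fx  <- load_fixture_tables()
jh  <- fixture_condition_targets(fx, "JH")
jv  <- fixture_condition_targets(fx, "JV")
cmp <- compare_conditions(jh, jv)
cmp
#> <mir_condition_comparison> JH vs JV
#>   common miRNA families: 8
#>   unique to JH: 3; unique to JV: 5
#>   shared targets: 25
```

Eight miRNA families occur in both conditions (11 total in JH, 13 in
JV); 25 target transcripts are shared, each with an up/down regulation
call from its FPKM pair. The curated query-gene selection reproduces
the ten genes taken into co-expression analysis:

```r
select_pcc_genes(cmp, rule = "packaged")
#> # A tibble: 10 × 3
#>    gene     target_key                              mirnas
#>  1 CMO      choline monooxygenase                   miR-156;miR-157
#>  2 RPS5     small subunit ribosomal protein s5      miR-4995
#>  3 RPL9     large subunit ribosomal protein l9      miR-5658
#>  4 EIF5     translation initiation factor 5b        miR-5021;miR-5658
#>  ...                                                miR-5021
```

The JV-side bipartite network and its degree correlation:

```r
bip <- build_bipartite(jv[, c("mirna", "target")], "JV")
bip
#> <mir_bipartite> [JV] 13 miRNAs, 55 targets, 61 edges
degree_correlation(bip)
#> <mir_degree_correlation> r = -0.5171 over 61 connexions
```

r < 0 says hub miRNAs (miR-5021, miR-5658) attach to low-degree
targets — the expected disassortative shape of a miRNA regulon.
Folding, discovery and simulation work the same way:

```r
fold_rna("GGGGGAAAACCCCC")
#> <mir_fold> 14 nt, 5 pairs, MFE -10.20 kcal/mol
#> GGGGGAAAACCCCC
#> (((((....)))))

sim <- make_transcriptome(simulation_config(seed = 7))
res <- identify_mirnas(sim$transcripts, sim$mature, condition = "JH")
res$inventory          # accepted families
autoplot(res$candidates$fold[[1]])
```

A thin command-line front-end over the same functions is installed at
`system.file("cli", "mirframe.R", package = "mirframe")` with
subcommands `identify`, `targets`, `network`, `gonet`, `coexpress`,
`simulate` and `run-all`.

## Package layout

| Area | Files |
| --- | --- |
| IO (FASTA, OBO, SIF/GraphML/TSV, expression) | `R/io-*.R` |
| Folding engine + hairpin geometry | `src/fold.cpp`, `R/fold.R` |
| Discovery, targets, networks, GO, co-expression | `R/discovery.R`, `R/targets.R`, `R/network.R`, `R/go.R`, `R/coexpression.R` |
| Synthetic data | `R/simulate.R` |
| Pipeline + config | `R/pipeline.R`, `R/config.R`, `inst/cli/mirframe.R` |
| Fixtures (published table transcriptions) | `inst/extdata/*.tsv` |

See `vignettes/mirframe-methods.Rmd` for the models, parameter
rationale and design notes.
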