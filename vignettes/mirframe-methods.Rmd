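---
title: "mirframe: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirframe: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirframe)
```

mirframe compares miRNA regulation between two transcriptome conditions
(the shipped fixtures describe a healthy, "JH", versus virus-infected,
"JV", plant tissue comparison) through six stages: input assembly,
homology-based miRNA discovery with hairpin validation, miRNA→mRNA
target scoring, miRNA–target network profiling, a GO node-score network,
and weighted co-expression reconstruction. This vignette explains the
models behind each stage, the parameters that matter, and the design
choices made where the underlying procedure was open to interpretation.

## The folding model

Precursor validation needs secondary structures, so the package carries
its own minimum-free-energy folder (`fold_rna()`). The model is a
deliberately simplified nearest-neighbour scheme:

* Watson–Crick (A:U, G:C) and G:U wobble pairs; N never pairs.
* Energy = sum of **stacking terms** for directly adjacent pairs, read
  from a 16-entry table over the four Watson–Crick pair types
  (`fold_energy_params()$stack_table`, kcal/mol); any stack involving a
  G:U pair contributes one fixed weak term (−0.5).
* Flat **loop penalties**: +3.0 per hairpin loop, +2.0 per bulge or
  internal loop. Multiloops and exterior bases are free.
* Hairpin loops keep at least 3 unpaired bases; structures are nested
  (no pseudoknots); bulge/internal loops are capped at 30 unpaired
  bases, the standard dynamic-programming restriction.

The A:U/U:A stacking entries are set to a uniform −0.9 so that a stem
containing only A:U stacks can never reach −20 kcal/mol: this keeps the
MFE acceptance criterion discriminative and makes the synthetic
`fail_mfe` construction provably weak whatever structure the window
folds into. The full-resolution Turner rules would change the absolute
energy scale; since the downstream criterion is a coarse −20 kcal/mol
threshold, the threshold is configurable and an external thermodynamic
folder (e.g. `RNAfold`) can be plugged in through the `backend` argument
of `fold_rna()` — the contract is a dot-bracket string plus an energy on
the last stdout line. All packaged tests and acceptance properties are
stated against the built-in model.

Optimality is resolved deterministically: the dynamic programme
minimises the pair `(energy, number of pairs)` lexicographically, and
the traceback walks its options in a fixed order, so co-optimal
structures always resolve to the same output. The folding engine is
validated against an independent exhaustive enumerator over every
nested structure (all sequences up to 8 nt exhaustively, plus 500
random sequences of length 9–12).

```{r fold-example}
fold_rna("GGGGGAAAACCCCC")
```

## miRNA discovery and the six precursor criteria

`find_mature_matches()` slides every mature reference sequence over
both strands of every transcript. Family assignment requires 100%
identity; windows with up to 4 mismatches are retained for folding and
carry a putative `miR-f…` label, reconciling the two mismatch tiers of
the homology protocol (identity for naming, a tolerance tier for
candidate folding). Each match gets an occurrence-expectation e-value,
`database_length × transcript_length × 4^−(matched positions)`, with a
default cutoff of 1e−5; the formula is documented configuration, chosen
because the protocol names a cutoff but not a statistic.

`extract_precursors()` cuts a window of ±120 nt (a typical plant
pre-miRNA span; configurable) and `evaluate_criteria()` applies six
named verdicts, whose conjunction is `accepted`:

1. `is_candidate` — the window holds a homology match.
2. `has_hairpin` — a stem of ≥ 12 pairs encloses a single terminal
   loop. The stem is the longest chain of pairs each enclosing exactly
   one child, so bulges and internal loops extend a stem but a
   multiloop ends it. Twelve pairs is the smallest stem that can still
   host a ~21-nt mature with fewer than seven mismatches.
3. `mature_in_one_arm` — every mature position classifies to the same
   arm of the maximal stem (`arm_of()`).
4. `duplex_mismatch_ok` — strictly fewer than 7 mature positions are
   unpaired or paired outside the opposite arm. When the mature does not
   lie in one arm the duplex is undefined; the flag is then vacuously
   true and rejection is carried by criterion 3 alone, which keeps the
   six flags diagnostically orthogonal.
5. `no_loop_or_break` — no mature base falls in the terminal loop, and
   no unpaired run of ≥ 3 bases splits the mature pairing block. This
   operationalises the qualitative "no loop or break" requirement; runs
   of 1–2 unpaired bases count as mismatches, not breaks.
6. `mfe_ok` — window MFE ≤ −20 kcal/mol.

## Target prediction

`score_duplex()` implements the plant small-RNA expectation score:
penalties per miRNA position (match 0, G:U wobble 0.5, mismatch 1.0,
gap 2.0), doubled in the core region (positions 2–13), summed over the
first 20 miRNA positions ("upsize"). At most one gap is allowed, placed
by exhaustive minimisation; a vectorised scanner (`predict_targets()`)
applies the same scheme across all candidate windows and keeps locally
optimal non-overlapping sites, the defaults being expectation ≤ 3 and
the top 200 sites per miRNA. A mismatch — not a wobble, not a gap — at
positions 9–11 calls `translational_inhibition`, otherwise `cleavage`;
treating a central wobble as inhibition is available as an alternative
convention but off by default, since the scoring scheme itself prices
wobbles below mismatches.

Target-site accessibility (maximum energy to unpair the site, default
parameter 25 with 17 nt upstream / 13 nt downstream flanks) is
implemented as `site_unpair_energy()` — the MFE difference between the
flanked region and the same region with the site forced unpaired — but
is **off by default**: the built-in energy model's absolute scale is not
comparable to partition-function unpairing energies, so the filter is
an opt-in hook rather than a default step. When off, the threshold
parameter is ignored with a warning.

## Networks: adjacency, bipartite views, degree correlation

`build_adjacency()` realises the binary interaction matrix
(`A[i,j] = 1` iff miRNA i targets transcript j) and
`build_bipartite()` its directed miRNA→target graph; the three analysis
variants (condition-A-unique, condition-B-unique, and common-miRNA
differential) are set-algebra selections over the per-condition tables.

Degree statistics run on the undirected view. The degree correlation

$$ r = \frac{M^{-1}\sum_i j_i k_i - \left[M^{-1}\sum_i \tfrac12 (j_i+k_i)\right]^2}
         {M^{-1}\sum_i \tfrac12 (j_i^2+k_i^2) - \left[M^{-1}\sum_i \tfrac12 (j_i+k_i)\right]^2} $$

is the standard degree-assortativity coefficient with each edge
contributing its endpoint-degree pair symmetrized. A star is perfectly
disassortative (r = −1); a regular graph has zero endpoint-degree
variance and r is undefined — returned as `NA` with a diagnostic rather
than a number. The implementation is checked against an independent
Pearson-correlation evaluator on **all** 27,475 connected graphs with at
most 6 nodes.

Expression correlation (`expression_pcc()`) offers two modes, because
"the PCC of the identical transcript across conditions from FPKM
values" is under-specified when each condition contributes a single
FPKM value: `replicate` mode correlates the two conditions' replicate
vectors of one transcript (needs ≥ 3 replicates), `profile` mode
correlates condition-mean vectors across a transcript set. The fixture
tables carry one FPKM per condition, so the fixture path uses the
packaged selection rule below rather than a per-transcript correlation.

### The packaged query-gene selection

The shipped fixture tables transcribe the published comparison: 47
common-miRNA target rows, 15 condition-unique rows, and the ten query
genes (CMO, RPS5, RPL9, EIF5, MVA1, PPC, PSAX, SUMO, CYP707A1, DXS)
with their co-expressed genes. Five of the ten queries are quantified
in only one condition, and no numeric FPKM threshold separates the
selected one-condition targets from the unselected ones; the selection
is therefore shipped as a curated symbol list (`rule = "packaged"` in
`select_pcc_genes()`), with `"both_conditions"` and `"all"` as
principled alternatives. The symbol-to-target synonym table is likewise
our own transcription. One fixture row (6.5) carries a regulation
arrow that contradicts its own FPKM values; `compare_conditions()`
follows the numeric rule (up iff the second condition's FPKM is larger)
and `validate_fixture_regulation()` reports the discrepancy instead of
silently editing it.

## GO node-score network

A term's node score is

$$ score(g) = \sum_{g_\alpha \in desc(g)} gp(g_\alpha)\,\alpha^{dist(g,g_\alpha)} $$

over the descendant closure of `g` through `is_a` edges, with `gp` the
per-term annotation count and `dist` the shortest descending path (the
DAG may offer several). Three choices were open:

* `desc(g)` **includes g itself** at distance 0 — otherwise a leaf term
  could never score, contradicting score-based prioritisation of leaf
  annotations.
* **α defaults to 0.6**: the decay is not given a value anywhere in the
  published description; 0.6 keeps two levels of descendants
  influential (0.36 at distance 2) without letting deep subtrees
  dominate, and it is exposed prominently in every relevant signature.
  At α = 1 the score degenerates to the subtree annotation total, which
  is the oracle used in tests.
* Only `is_a` edges are traversed; `part_of` support would be a flag,
  off by default, on DAGs that carry it.

Transcripts are scored as the sum of node scores of their direct
annotations in one namespace, clustered by equal score (relative
tolerance 1e−9 — "same score" up to floating point), and clusters are
linked with weights equal to the number of GO terms shared between
their members' annotation sets. Shared-term weighting was chosen over
score-difference weighting because cluster interconnection "based on
the node score association" most plausibly means shared ancestry of the
annotations; the alternative would make edge weights a function of the
very quantity that separates the clusters.

## Co-expression reconstruction

For each query gene, every candidate receives three component scores in
[0, 1]: rank-normalised mean abundance across the candidate pool,
Jaccard overlap of direct GO annotation sets, and `(PCC + 1)/2` across
all (condition, replicate) samples. The published description names the
components and their weights (abundance 0.4, GO 0.3, PCC 0.3, "out of
total score 1") but not the normalisations; rank, Jaccard and rescaled
correlation are this package's choices, each replaceable by supplying
pre-computed component columns to `combined_score()`. The weighted-sum
reading (weights × normalised scores) was implemented rather than
"component value capped at its weight", because only the former makes
the components commensurable and the total equal 1 at the maximum.
The top `k = 20` candidates per query (ties broken by gene id for
determinism) form the undirected co-expression network.

## The synthetic-data generator

`simulation_config()` fixes the study conditions for all generated
inputs; a single integer seed makes every output byte-reproducible.

* **Transcriptomes** (`make_transcriptome()`): background transcripts
  uniform over {A,C,G,U} (minimising accidental hairpins), 400–900 nt,
  20 per run — enough to exercise matching, windowing and ranking at
  desk scale. Planted precursors follow five compliance profiles;
  each is *engineered* so exactly the intended criterion fails:
  `fail_mfe` uses an A/U-only stem (bounded above −15 kcal/mol under
  the model), `fail_arm` puts the mature in a single-stranded tail
  30 nt outside an inert C/G hairpin, `fail_mismatches` and `fail_loop`
  use U-free windows where mismatch positions are A:A oppositions that
  cannot pair and the helix blocks alternate GG/CC so a shifted
  register cannot pair at all. Because a folding model may still
  rearrange a self-similar construct, each plant is verified against
  its intended flag pattern at generation time and redrawn under the
  seed if needed; the truth table records coordinates and intended
  verdicts as first-class output.
* **Expression** (`make_expression()`): log-normal FPKM,
  `log FPKM = μ_g + b z + σ ε` with a latent factor `z` shared within
  each planted group and loading `b = σ√(ρ/(1−ρ))`, so the log-scale
  pairwise correlation is the configured ρ (default 0.95, σ = 0.3,
  5 replicates; with σ = 0 a fixed loading keeps the degenerate case
  exactly correlated). With σ = 0.3 the log-normal transform shifts
  FPKM-scale correlations by well under 0.01.
* **GO** (`make_go()`): a layered random DAG (acyclic by construction,
  25 terms, depth 3), annotations over the deepest layer, with direct
  per-term counts emitted as truth.

What the generator does **not** emulate: sequencing error, expression
dependence on miRNA targeting (FPKM values are independent of the
planted precursors), isoform redundancy, and genome-scale transcript
counts. Passing the planted-recovery tests therefore demonstrates that
the pipeline's logic is faithful to its own criteria on inputs where
ground truth is known — not that the criteria themselves recover every
real precursor, which also depends on the energy model and on dataset
scale. The published dataset-dependent counts (39/61 predicted targets,
50/74 network nodes) require the original transcriptomes and external
tool behaviour and are deliberately not asserted; the family-level
fixture counts (11 JH, 13 JV, 8 common, 10 query genes) are.

## Numerical and scale choices

* Folding ties: `(energy, pair count)` lexicographic, deterministic
  traceback order; energies compared at 1e−7.
* Degree-correlation denominator below 1e−12 → `NA` with a message.
* Score clustering tolerance is relative (`|a−b| ≤ tol·max(1, |a|)`).
* Problem sizes in the shipped tests: exhaustive folding oracle to 8 nt
  plus 500 random 9–12-mers; all 27,475 connected ≤ 6-node graphs; 100
  random DAGs; planted recovery at 50 replicates. These sizes keep the
  whole suite in a few minutes on one core while leaving every check
  exhaustive or heavily replicated at its scale.

## Known limitations

* The built-in energy model ranks structures sensibly but its absolute
  energies are not Turner-accurate; conclusions tied to the −20 kcal/mol
  bound transfer to other folders only after re-calibrating the
  threshold.
* The e-value is an occurrence expectation, not a Karlin–Altschul
  statistic; cutoffs are not comparable to BLAST e-values.
* `select_pcc_genes(rule = "packaged")` reproduces a published,
  curated selection and should not be used on new datasets; use
  `"both_conditions"` there.
* GO scoring ignores `part_of` and cross-namespace relations.
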