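---
title: "Censusing lichen metagenomes: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censusing lichen metagenomes: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichencensus)
library(dplyr)
```

## The problem

A lichen metagenome is a shotgun library of everything in a thallus: the
dominant lichen fungal symbiont (LFS), one or more photobionts (green algae
and/or cyanobacteria), basidiomycete yeasts, and a community of bacteria.
Collections of such metagenomes are increasingly used to argue for or
against the presence of particular symbionts, but detection is strongly
confounded by sequencing depth, genome size, cellular abundance, and strain
heterogeneity. This package implements the bookkeeping and the models needed
to census such a collection honestly: who is present, at what frequency, on
which detection tier, with what metabolic capabilities — and what
*cannot* be concluded, namely absence.

The package operates downstream of assembly, binning, and annotation. Its
inputs are tables: per-sample breadth and depth of coverage of each
species-representative MAG (metagenome-assembled genome), genome quality
scores, taxonomy lineages, KO (KEGG Orthology) annotations, two-tier SSU
rRNA screening calls, a sample manifest, and pairwise ANI/AF (average
nucleotide identity / alignment fraction) records.

## Presence calling and the dataset cascade

A species is **present** in a metagenome when at least 50% of its genome's
positions are covered by mapped reads (`call_occurrence()`, inclusive at
the boundary — "at least 50%"; the threshold is an argument). Breadth is
interpreted as the fraction of positions with one or more reads, counting
overlapping reads once. Depth of coverage is `n_reads * read_length /
genome_length` (`depth_of_coverage()`), and a symbiont's relative abundance
is its depth divided by the LFS depth (`relative_abundance()`).

Collections shrink in documented stages. Duplicated archive deposits are
removed first (`deduplicate_samples()`), keeping one sample per connected
duplicate group — the flagged one if a `keep` column says so, else the
lexicographically smallest id, so the reduction is reproducible. **Dataset
1** comprises samples with at least one present MAG; **Dataset 2** the
subset whose LFS call survived verification. LFS assignment takes the
deepest present fungal MAG (the dominant fungus has the deepest coverage),
with lexicographic tie-breaks. Verification compares the declared lichen
name, resolved to an expected fungal genus through a user-supplied name
map, against the MAG's lineage. We replaced manual phylogenetic-tree
inspection with this lineage-consistency rule because tree reading cannot
be automated faithfully; conflicts are *flagged* (`misassigned`), never
silently resolved. Two resolvable conflict classes are recognized: a
second present fungal MAG matching the declared name (`reassigned`), and a
library name contradicting the organism field (`name_corrected`).
MAGs from misassigned samples stay in overall occurrence counts; the
status column lets downstream stages exclude them, which the cascade does
for Dataset 2.

## Quality scores and dereplication

Genome quality is `completeness − 5 × contamination`; catalogue inclusion
requires a score of at least 50 (QS50, inclusive). The stricter
"near-complete" tier used for functional annotation is completeness ≥ 95%
and contamination ≤ 10%, both inclusive and configurable — sources differ
on strictness at these boundaries, so the bounds are arguments rather than
constants.

`dereplicate()` collapses MAGs into species-level clusters at 95% ANI,
with an alignment-fraction floor of 30% (prokaryotes) or 40% (eukaryotes).
We chose greedy, score-ranked centroid clustering (each MAG joins the
first already-founded representative it matches, in descending quality
order with id tie-breaks) rather than single linkage: it mirrors how
dRep-style dereplication picks representatives, is order-deterministic,
and cannot chain distant genomes into one species. AF is symmetrized as
the maximum of the two directions; a pair missing from the ANI table is
treated as a non-match.

## Census statistics

Frequency is the total number of occurrences of a group across the data
set; groups above species level sum their member lineages, and MAGs
without a genus name are tabulated as `"<Family> gen. sp."`
(`tabulate_frequency()`). Prevalence percentages are integers, rounded
half away from zero — R's default half-to-even rounding would disagree
with conventionally printed percentages at .5 boundaries, and a single
fixed convention keeps outputs deterministic. Rankings break ties
alphabetically (`rank_and_select_top()`).

Detection is recorded on three tiers — MAG recovery, SSU rRNA in the
assembly, SSU rRNA in raw reads — with no inference across tiers
(`merge_detection_tiers()`): a MAG hit with no rRNA hit stays exactly
that. Joint outcomes (`mag_and_rrna`, `mag_only`, `rrna_only`,
`not_detected`) are ordered against sequencing depth
(`classify_detection_outcome()`, `plot_detection_depth()`). Co-occurrence
networks (`build_cooccurrence()`) weight each lineage pair by the number
of metagenomes in which both are present, omitting zero-weight pairs and
never-present lineages; heatmap-style summaries reduce to tables with a
minimum-group-size filter (default 4).

## The KEGG module engine

Module definitions are boolean expressions over KOs organised into
sequential blocks. The grammar (`parse_module_definition()`): top-level
spaces separate blocks; commas separate alternatives and bind *looser*
than spaces inside parentheses; `+` joins obligatory complex subunits;
`-`-prefixed components are optional and carry no requirement; `--` is a
missing-step placeholder treated as an always-absent leaf; `M#####` leaves
reference other modules and must be resolved through an explicit mapping —
evaluation raises rather than guessing. Completeness is the fraction of
top-level blocks satisfied by a genome's KO set
(`module_completeness()`). Parsing and serialization form a fixed point,
and the evaluator is tested exhaustively against an independent
truth-table oracle on all subsets of definitions with ≤ 4 KOs, plus 1,000
randomized monotonicity chains.

"Partial completeness, allowing one missing gene" is interpreted
literally at the gene level: a module qualifies when adding a single KO
would complete it (`partial_one_missing()`). A per-block reading would be
more permissive; since the phrase says *gene*, the single-KO rule is the
default and the block-fraction is available separately from
`module_completeness()`.

## Vitamin trophy and cross-feeding

Rules name the qualifying routes per vitamin (`vitamin_rules()`): biotin
ring assembly via module M00123 or the alternative M00950 (the pathway for
the pimelate moiety is deliberately out of scope — its enzymes are too
diverse for reliable screening, so the rules target the conserved
ring-assembly modules only); thiamine synthesis (M00127) and salvage
(M00899 or the thiMDE three-gene conjunction); cobalamin synthesis via
M00122 (prokaryotes) or M00925 (eukaryotes). A genome is a **prototroph**
when any synthesis route is complete, **salvage_only** when only a salvage
route is, **partial** when its best route fraction is strictly between 0
and 1, else **auxotroph**. Whether "complete" should tolerate one missing
gene is genuinely ambiguous in practice, so both readings are computed
side by side (`*_one_missing` columns) and the strict one decides the
status. metE/metH screening feeds `classify_cobalamin_dependence()`:
metE only → independent, both → facultative, metH only → dependent,
neither → unknown.

Cross-feeding is assessed only in metagenomes with a near-complete MAG
for each of three roles — LFS, photobiont (alga *or* cyanobacterium; in
tripartite lichens either partner counts), and a focal bacterium
(`select_highly_complete_metagenomes()`). For each vitamin the LFS cannot
synthesize, co-occurring prototrophs are listed as candidate providers
(`assess_complementarity()`); organisms with partial pathways are reported
separately and never count as complementing — the stricter reading, since
complementation claims should rest on complete routes.

The package ships *synthetic* module definitions and rules
(`synthetic_module_library()`, `synthetic_vitamin_rules()`, KO ids in the
K90xxx range) for simulation and testing; real KEGG definition content is
licensed and must be supplied by the user.

## The simulator

`simulate_community()` and `generate_bundle()` emit every input table from
a configurable, seeded model, so the whole pipeline is testable without
sequence data. The study conditions encoded in the defaults:

* **Depths** are log-uniform over `1e6`–`1e12` bp — six orders of
  magnitude, the span published lichen metagenomes cover — with
  `read_length = 150`.
* **Expected per-base depth** of an organism is
  `total_depth_bp × mass_fraction / genome_size`
  (`depth_for_organism()`).
* **Breadth** follows the Lander–Waterman expectation `1 − exp(−c)`, with
  strain mixtures penalized by dividing effective depth by
  `strain_multiplicity^penalty` (`breadth_from_depth()`, default exponent
  1). No quantitative model of strain-mixture effects on assembly exists;
  this is the simplest form with the right qualitative behaviour
  (monotone in depth, anti-monotone in multiplicity), and the exponent is
  a config knob, not a claim.
* **rRNA detection** (`rrna_detected()`): the expected number of reads
  overlapping the rRNA loci is
  `depth × copies × (rrna_length + read_length − 1) / read_length`; the
  read tier fires when a Poisson draw with that mean reaches `min_reads`
  (default 1) *or* when the genome itself passes the breadth gate — a
  genome covered broadly enough to be recovered necessarily has reads
  over its multicopy rRNA loci, so the coupling makes the detectability
  ordering (read tier ≥ MAG recovery at every depth) hold by
  construction rather than only in expectation. The assembly tier
  additionally requires effective depth ≥ 1 as an assemblability proxy,
  so read ≥ assembly always. Organisms with zero rRNA copies are never
  detected — mirroring real MAG-only lineages absent from rRNA reference
  databases, which is also why tier-ordering comparisons are restricted
  to screenable taxa.
* **Community structure**: one LFS per sample (35-Mb genome, ~60 rDNA
  copies, 45–70% of sample DNA), drawn from a pool of lecanoromycete
  species so some samples share an LFS; a strain-mixed *Trebouxia* alga
  (55–60 Mb, multiplicity 2, ~300 rDNA copies); a single-strain *Nostoc*
  (7 Mb); basidiomycete yeasts at the ~1:100 coverage regime relative to
  the LFS; and a dozen bacteria (4–6 Mb) from the high-frequency lichen
  families, two of them without rRNA annotations. Mass fractions are
  drawn per sample and rescaled if they would exceed 0.98.
* **Artifacts**: the configured number of duplicate deposits (coverage
  and rRNA rows byte-identical to their source) and misidentified
  samples (declared name swapped to a different genus).
* **Determinism**: all randomness flows through the single config seed;
  regeneration under the same config is byte-identical.

Organisms carry planted trophy statuses realized as KO sets against the
synthetic module library, so classification can be checked for exact
recovery.

What the simulator does **not** emulate: read-level errors, assembly
graphs, chimeric bins, contamination between bins, phylogenetic signal,
or biased DNA extraction. Passing tests therefore demonstrate that the
*census logic* is correct under the stated coverage model — not that any
upstream assembly/binning stack is reliable on real data.

Two deterministic fixtures complement the simulator:
`simulate_cascade_fixture()` encodes a 480-sample collection with 43
duplicate pairs, 62 zero-MAG samples, 348 fungal-MAG samples and 18
misidentifications (reducing to 437 → 375 → 330), and
`simulate_census_fixture()` builds a 674-species bacterial catalogue
(16 phyla, 1,000 occurrences, 13 dominant genera) for the frequency and
share arithmetic. `simulate_annotated_mags()` plants trophy statuses in a
63-genome annotation set.

## Numerical choices and degenerate inputs

* Thresholds are inclusive where sources say "at least"/"≥": breadth 0.5,
  QS50, ANI/AF minima, near-complete bounds.
* Ties break lexicographically everywhere (LFS depth ties, ranking ties,
  dereplication order), so outputs never depend on input row order.
* Integer percentages round half away from zero.
* A zero LFS depth makes relative abundance undefined (`NA`), not zero.
* Empty duplicate-pair lists, empty rRNA tables and genomes with no KO
  annotations are valid inputs (no-ops / all-false / auxotroph).
* A module whose definition has no non-optional block has undefined
  completeness and errors; unresolved `M#####` references error rather
  than defaulting.
* Malformed tables fail fast with the offending row and column named
  (`read_census_table()`).

## Problem sizes used in the tests

The shipped suite runs the full pipeline on bundles of 40–100 samples and
about 47 organisms, sweeps 50–60 log-spaced depths at 200 replicates for
the detection-ordering property, enumerates all subsets of every
definition with ≤ 4 distinct KOs for the module-engine oracle, and checks
dereplication against its reference assignment on 20 random tables of up
to 15 genomes. These sizes exercise every code path at full statistical
structure; the algorithms themselves are linear to quadratic in their
inputs and handle collection-scale tables (hundreds of samples, a
thousand species) directly, as the cascade and catalogue fixtures show.

## Known limitations

* Lineage-consistency at genus rank is a coarser verification than manual
  tree placement; finer mismatches (within-genus misidentification) pass
  unflagged.
* The strain penalty is illustrative; do not interpret its exponent
  biologically.
* The simulator's rRNA model ignores reference-database coverage except
  through the zero-copy mechanism.
* Statistical tests on relative occurrence frequencies are deliberately
  absent: with sequencing depth uneven across samples, such tests would
  be confounded, so the package reports counts and shares only.

## A short worked run

```{r worked-run}
cfg <- simulation_config(seed = 1, n_samples = 60, n_duplicate_pairs = 4,
                         n_misidentified = 2)
bundle <- generate_bundle(cfg)
run <- run_census_pipeline(bundle)
glance(run)
head(run$frequency, 5)
run$complementarity |>
  dplyr::count(vitamin, lfs_status, complemented)
```
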