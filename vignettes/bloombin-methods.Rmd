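---
title: "Consensus taxonomic binning and functional profiling of bloom metagenomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus taxonomic binning and functional profiling of bloom metagenomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloombin)
library(dplyr)
```

Coastal spring phytoplankton blooms trigger a rapid succession of
heterotrophic bacterioplankton — *Flavobacteriia* such as *Polaribacter*,
*Formosa* and *Ulvibacter*, and *Gammaproteobacteria* such as *Reinekea* —
that degrade the algal polysaccharide pulse. Resolving who responds and
with which gene repertoire requires (i) assigning metagenome contigs to
taxonomically coherent bins ("taxobins"), (ii) annotating
carbohydrate-active enzymes (CAZymes), sulfatases and transporters, and
(iii) relating clade abundances to environmental drivers. `bloombin`
implements that analysis chain as composable, tested R functions, and
pairs it with a seeded synthetic-data generator so every stage can be
validated against a known ground truth without any sequence downloads.

This vignette records the methods, the tunable parameters, and the design
decisions that were genuinely open.

## Taxonomy representation

All classifiers vote over seven canonical ranks — superkingdom, phylum,
class, order, family, genus, species — with a synthetic rank-less root
above superkingdom so "unclassified" is representable as an empty lineage.
`load_taxonomy()` accepts NCBI-taxdump-like nodes/names tables and
*projects* the tree to those seven ranks: nodes at intermediate ranks
(suborder, tribe, "no rank") are removed and their children re-attached to
the nearest canonical ancestor. Projection is our choice of normalisation;
the alternative — keeping intermediate ranks and skipping them during
voting — complicates every downstream vote for no representational gain.
After projection the package enforces that each node's parent is exactly
one rank shallower; taxonomies violating that (e.g. a genus directly under
an order) are rejected rather than silently patched, since a gap would
make per-rank votes incomparable across hits.

Lineages are ordered taxon-id vectors (length 0–7); `lca()` is the longest
common prefix. Tables serialise lineages as semicolon-joined names, which
therefore must be unambiguous within a tree.

## Rank-progressive weighted classification of genes

`classify_gene()` implements a bit-score-weighted vote that descends the
ranks. At rank $r$, each surviving protein hit contributes its bit score
to its reference taxon's ancestor at $r$; with $W(t)$ the summed score of
taxon $t$ and $W$ the total over hits that resolve rank $r$, the winning
taxon is fixed iff

$$f_r = \max_t W(t) \, / \, W \; \ge \; t_r ,$$

after which hits outside the winner's subtree are discarded and the walk
continues; otherwise it stops and returns the lineage assembled so far.
Upstream, `filter_hits()` applies the hit-table post-processing the method
assumes: E-value at most `1e-10` and at most 500 hits per gene, highest
bit scores first.

Decisions that the verbal description of such progressive classifiers
leaves open, fixed here and configurable where meaningful:

* **Threshold schedule.** $t_r$ must be non-decreasing with depth (the
  vote gets stricter as it descends). The published description calls the
  thresholds adjustable without stating values, so the package ships
  defaults of 0.50, 0.55, 0.60, 0.65, 0.70, 0.80, 0.90 from superkingdom
  to species (`kirsten_thresholds()`), every value overridable.
* **Denominator.** $W$ counts only hits whose reference lineage resolves
  rank $r$ (after subtree restriction). Hits annotated only to a shallow
  rank therefore abstain from deeper votes rather than vetoing them — a
  shallow but consistent reference should not cap the depth a deep,
  dominant reference supports.
* **Ties.** Two taxa sharing the maximal weight stop the walk at the
  previous rank. This is conservative and deterministic without imposing
  an arbitrary taxon order.
* **Equality.** $f_r = t_r$ passes (the comparison is $\ge$).

Four properties pin the implementation down and are enforced by tests: an
exhaustive, independently coded vote-table oracle agrees exactly on 1,000
random hit tables; raising any threshold never deepens the result; adding
a hit that extends the current result never shortens it; and rescaling all
bit scores changes nothing.

## Mapping-derived path evidence

Reads mapped to reference sequences at $\ge$ 95% identity (inclusive) are
back-mapped to the contigs they assembled into; each contig thereby
accumulates read support for one or more taxonomic paths. Paths supported
by fewer than 1% of a contig's mapped reads are discarded
(`contig_paths()`), with the denominator taken as the contig's pre-filter
mapped-read total — "1% of the reads of a given contig" reads most
naturally as all of its reads. Evidence from separate reference sets
(curated genomes, a habitat-specific protein set) is filtered per source
and then concatenated by summing counts (`merge_path_sources()`), without
re-applying the 1% rule; applying the rule before concatenation matches
the order in which the upstream pipeline describes the two steps, and a
flag-level switch would only matter for paths within a factor of two of
the floor. Multi-mapping resolution is out of scope: the generator emits
one best reference per read.

## Contig-level consensus

`consensus_contig()` consolidates per-gene lineage predictions from any
number of predictors plus the mapping evidence into one lineage per
contig, by the same per-rank progressive vote with predictor weights in
place of bit scores. The published description ("a weighted assessment on
seven selected ranks") does not fix the arithmetic, so the scheme here is
a documented reconstruction with every constant exposed:

* each gene-based predictor speaks with **one voice per contig**: at rank
  $r$ its vote goes to the taxon named by the plurality of its genes
  (among genes consistent with the lineage fixed so far); an internal tie
  abstains. Aggregating first prevents gene-rich contigs from drowning
  the mapping evidence;
* the mapping evidence enters as one pseudo-predictor (id `"mapping"`,
  default weight 1.0 — parity with each gene-based predictor) whose
  weight is split over taxa proportionally to path read counts;
* the rank is fixed iff the top taxon's share of cast weight meets the
  rank threshold (same schedule type and defaults as the gene classifier,
  keeping one knob); that share is recorded as per-rank support;
* evidence contradicting an already-fixed ancestor abstains at deeper
  ranks; ties stop the walk.

Unanimity yields the common lineage with support 1.0 at every rank;
rescaling all weights changes nothing; and the consensus is always a
prefix of some evidence lineage. One subtlety surfaced by testing:
removing a predictor that agrees with the consensus at every *assigned*
rank can still lengthen the result, because below the stop rank that
predictor may have been party to the tie that caused the stop. The
monotone-truncation property is therefore only guaranteed — and only
asserted — for predictors whose lineage equals the consensus exactly, so
that they abstain below it.

`consensus_all()` drives the vote per contig and summarises, via
`glance()`, the fraction of contigs at or above a length floor (default
1 kbp) that received a non-empty lineage — the headline coverage figure
of a binning run.

## Consensus CAZyme annotation

A gene is annotated with a CAZyme family only when at least two of three
evidence sources — BLAST against CAZy, and HMM searches against dbCAN and
Pfam — report the same family label after per-family E-value filtering,
and the gene's contig is at least 500 bp (both boundaries inclusive).
Congruence is defined at the family-label level; requiring positional
overlap of the supporting alignments would need coordinates the evidence
tables do not carry, and family labels are already the unit of the
downstream profiles. Cross-database label mapping (Pfam clans vs CAZy
families) is the user's responsibility via the hit tables' `family`
column. Curated per-family cutoffs are user data: the package ships a
template (`read_cutoff_table()`, default `1e-5` everywhere) with
per-family override syntax. Sulfatases, TonB-dependent transporters
(TBDT) and TRAP transporters are called from Pfam evidence alone at a
flat `1e-5` cutoff (`pfam_family_calls()`); these families are
well-separated single-domain models for which multi-source consensus adds
nothing.

The 2-of-3 rule is verified exhaustively: over all 27 combinations of
absent / present-passing / present-failing per source, a call occurs
exactly when at least two sources are present-passing.

## Coverage-weighted gene frequencies

The frequency of a gene category is its coverage-weighted percentage:

$$\mathrm{freq} = 100 \times
  \frac{\sum_{g \in \text{targets}} \mathrm{cov}(g)}
       {\sum_{g \in \text{all}} \mathrm{cov}(g)} .$$

A gene's coverage defaults to its contig's mean coverage (per-gene depth
can be supplied as an optional column but is rarely available).
`family_profile()` evaluates this per family, community-wide and per
taxobin; per-bin profiles restrict numerator *and* denominator to the
bin's own genes, so they read as within-clade repertoires. The
community denominator is all predicted genes (not only annotated ones).
Genes with several family calls count in each family's numerator, so only
partitions of genes — not overlapping family sets — must sum to 100%.

For bin visualisation, `gc_coverage_filter()` reproduces the standard
contig-selection geometry: platform-specific length floors (2,750 bp for
pyrosequencing assemblies, 15,000 bp for Illumina), a 20–60% GC window,
exclusion of sparse very-high-coverage contigs — quantified here as the
99th coverage percentile, configurable, since no number is standard — and
bubble radii proportional to contig length (`plot_gc_coverage()`).

## 16S tag tables

`subsample_reads()` draws a seeded uniform subsample of 40,000 tags per
sample (samples with fewer reads are kept whole — discarding them would
bias against low-biomass dates, and up-sampling fabricates reads). An
OTU's best database match is accepted when
$(\text{identity} + \text{coverage})/2 \ge 93$ (percent, inclusive);
failing OTUs carry empty taxonomy. `collapse_to_genus()` sums read counts
over OTUs sharing a lineage truncated at genus — species-level
assignments are cut back to genus before collapsing, shallower lineages
collapse at their deepest rank, and unclassified OTUs aggregate into one
row — yielding a taxa-by-samples matrix that conserves total reads.
Upstream dereplication and 98% clustering are consumed as given: the
package starts from the clustered OTU table.

## Abundance–environment statistics

Clade and phytoplankton abundances are log-transformed
(`log_transform()`, $\log_{10}(x + 1)$; the pseudocount handles zero
counts and is configurable). `spearman_matrix()` computes Spearman's
$\rho$ with average ranks and two-sided p values per (clade, variable)
pair on pairwise-complete observations, via `stats::cor.test()` — exact p
for small tie-free samples, verified against an all-permutation oracle for
$n \le 7$. Constant series yield `NA` rather than an arbitrary value.

`stepwise_forward()` builds a linear model by repeatedly adding the
candidate with the smallest partial-F p value while it is below `p_enter`
(default 0.05). The partial-F entry rule follows the convention of the
desktop statistics tools classically used for such analyses; an
AIC-based entry is available behind `criterion = "AIC"`. No
multiple-testing correction is applied to the correlation table by
default, mirroring how such screens are conventionally reported; a
Benjamini–Hochberg adjustment is one `p.adjust()` call away on the tidy
output. Note that with `p_enter` $= \alpha$, a pure-noise candidate
enters with probability exactly $\alpha$ — that is the designed
false-entry rate, not a defect.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `make_taxonomy()`,
`simulate_metagenome()` and `simulate_timeseries()` are deterministic
given the seed. The generator emulates exactly the statistical structure
the pipeline assumes:

* a balanced seven-rank taxonomy (default: two children per node) with a
  few genus labels echoing recurrent bloom responders for readable
  fixtures;
* genus-level taxon bins with geometrically spaced abundances and GC
  means spread over 30–52%, so GC-coverage clusters exist by
  construction; contig coverage is proportional to bin abundance with
  lognormal noise (sd 0.3 on the log scale);
* 50 contigs of 10 genes each by default; each gene draws 8 protein hits
  which point to its true species with probability $1 - p_{err}$
  (default $p_{err} = 0.1$) and otherwise to a random other species. Bit
  scores follow a two-component model (true hits $\mathcal{N}(150, 15)$,
  decoys $\mathcal{N}(80, 15)$): the classifier consumes only bit
  scores, so alignment-level realism would add nothing to the test;
* three CAZyme evidence sources detect a gene's true family with
  per-source sensitivities (0.9, 0.9, 0.7 for CAZy-BLAST, dbCAN, Pfam),
  commit false positives at rate 0.02, and also emit deliberately weak
  hits that the cutoff filter must remove;
* read mappings with Gaussian identity noise around 97% (sd 1.5), so a
  realistic fraction falls below the 95% floor, plus the read-to-contig
  back-map;
* clade-abundance time series over 30 samples with one planted monotone
  driver per clade at signal-to-noise
  `effect_size / noise_sd` $= 1 / 0.5 = 2$, a bloom-shaped chlorophyll
  *a* curve, declining nutrient ramps; and an OTU table in which a
  planted 20% of OTUs fail the 93% similarity rule.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: sequence-level homology and
alignment artefacts, chimeric contigs and assembly error, reference
databases that are wrong rather than merely incomplete, multi-mapping
reads, compositional coupling between clade abundances, and primer or
chemistry biases in tag data. Recovery rates on this generator validate
the algorithmic machinery, not the field performance of the upstream
tools.

## Problem sizes and numerical choices

The shipped test suite runs the vote-table oracle on 1,000 random hit
tables over trees of roughly 15–40 nodes, 500-case monotonicity and
consensus-invariance sweeps, the 27-pattern CAZyme truth table against 5
random cutoff tables, 100-replicate planted-sign and driver-selection
experiments, and the 50-contig end-to-end recovery — sizes chosen so the
full suite completes in about a minute while every randomized property
still has real statistical teeth. Exact comparisons are used wherever the
arithmetic is exact (integer bit scores in random tables keep vote sums
float-exact); frequency-closure checks use a 1e-9 tolerance.

`scripts/acceptance.R --seed <s> --out <path>` re-runs the end-to-end
experiments from scratch and writes the measured quantities as JSON; the
README describes the output fields.
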