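---
title: "Benchmarking targeted-metagenomics pipelines with ground-truthed simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking targeted-metagenomics pipelines with ground-truthed simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconbench)
```

## The problem

Targeted metagenomics (16S rDNA amplicon sequencing) profiles a microbial
community by amplifying a marker region and classifying the resulting
reads. Many analysis pipelines exist — clustering-first tools that build
OTUs and classify representatives, and assignment-first tools that
classify every read by k-mer or mapping — and their outputs differ enough
that the choice of pipeline, reference database, amplified region and
sequencing throughput all shape the biological conclusions. Judging a
pipeline requires datasets whose composition is known *exactly*, at the
level of every read.

`ampliconbench` provides the three legs of such an evaluation:

1. **Simulation** — ground-truthed amplicon datasets of controlled
   community complexity, throughput and error profile, with a truth table
   linking every read to its source genome and taxon;
2. **Scoring** — read-level precision/recall/F-measure at fixed ranks,
   richness (Chao1) and diversity (Shannon, Inverse Simpson) recovery,
   and information-theoretic partition agreement (NMI, AMI, 1-NID);
3. **Comparison** — cross-pipeline profile matrices, UPGMA clustering,
   Bray-Curtis distances, PCoA and rank-sum tests.

Running the six pipelines themselves (and their multi-gigabyte reference
databases) is out of scope: users bring per-read assignment tables in a
three-column TSV, and a fixture generator supplies marker-bearing
synthetic genomes plus a toy taxonomy so the whole protocol is testable
offline.

## The simulation model

### Community designs

A `community_design()` assigns each genome a weight. Three standard
complexity patterns are built in:

* **LC** (low): one dominant organism at 30% of reads, the rest equal;
* **MC** (medium): four dominant organisms at 20% each, the rest equal;
* **HC** (high): all organisms equal.

Reads are apportioned by largest-remainder (Hamilton) allocation with
lexicographic tie-breaking, so a 25,000-read LC dataset gives the
dominant genome *exactly* 7,500 reads, deterministically. Dominant
proportions are therefore recovered without Monte-Carlo error, and two
runs of the same design always agree.

### In-silico PCR

`find_amplicons()` scans both strands for exact matches of the forward
primer and, downstream, the reverse primer's reverse complement. IUPAC
degeneracy in the primers is expanded; an `N` in the template never
satisfies a primer base (a conservative choice — an undetermined template
base is not evidence of a primer site). **No mismatches are tolerated**,
so genomes whose primer sites have diverged simply fail to amplify; the
simulator drops them from the design with a warning and renormalizes the
remaining weights, which is exactly how real mock communities lose
species at the PCR step. Each forward site yields at most one product —
the shortest in-range one — with a 5,000 nt product-length guard against
runaway matches. Amplicons include both primer sites, matching how
amplicon sizes are conventionally quoted (~200 bp for V3, ~400 bp for
V4–V5).

### Read length and error model

Each read derives from one amplicon, drawn uniformly among the source
genome's marker copies (no copy-number weighting beyond multiplicity).
The corruption model is indel-dominated, as in Ion Torrent data, with
defaults of 0.01 deletions, 0.005 insertions and 0.005 substitutions per
base and a 20 bp read-length standard deviation:

* **Length.** A target length is drawn from
  `Normal(amplicon length, length_sd)` and rounded (floor 1 bp). Shorter
  targets truncate the 3' end of the amplicon. Longer targets keep the
  whole amplicon and append uniform random bases — emulating sequencing
  past the amplicon into adapter, a real single-end artefact. We chose
  this two-sided model deliberately: clamping read lengths at the
  amplicon length would place the mean of the draw *at* the clamp, so
  half of all draws would clamp and the realized length SD would
  collapse to ~58% of the nominal parameter. With the two-sided model
  the realized SD equals `length_sd` whenever the amplicon is much
  longer than the spread, which is what the stated "20 bp standard
  deviation from the amplicon size" means operationally.
* **Per-base events.** Each base suffers at most one event, drawn with
  probability `rate * w(i)` where `w` is a linear ramp in read position.
  With `end_bias = 0` the ramp is flat; the default `end_bias = 1` ramps
  from ~0x at the 5' end to ~2x at the 3' end, reflecting the known
  degradation of quality toward read ends on this platform. The ramp is
  **mean-normalized**, so the realized genome-wide event rates equal the
  nominal rates for any bias — the bias redistributes errors along the
  read, it does not add any. Substitutions draw uniformly from the three
  alternative bases; insertions add one uniform base after the position.
  Event counts are recorded exactly in the truth table.
* **What is not modelled.** Homopolymer-specific indel inflation,
  chimeras, PCR amplification bias, flowgram/quality simulation and
  paired-end reads are all out of scope. The published settings the
  defaults mirror specify only global per-base rates, and the positional
  ramp is this package's declared stand-in for "errors increase toward
  read ends", not a claim about any particular simulator's internals.
  Consequences: pipelines whose behaviour hinges on homopolymer error
  structure or chimera filtering will look better on these simulations
  than on real Ion Torrent data.

FASTQ qualities are a constant `I` (Q40) placeholder; the protocol
evaluates raw reads without quality filtering, so qualities are never
consumed. Determinism is by a single seeded RNG stream per
`simulate_dataset()` call: the same seed and inputs give byte-identical
FASTQ and truth files (generation is serial).

### Fixture genomes

`generate_fixture_collection()` builds synthetic genomes embedding 1–k
copies of a marker: conserved primer sites flanking a variable region
derived hierarchically (one random template per family, ~10% mutated per
genus, ~2% per species), so divergence is larger across families than
within genera — the property rank-level evaluation needs. Markers land
on either strand inside random background. This emulates the *structure*
real 16S data has (conserved flanks, rank-correlated variable regions,
multi-copy markers) but not its content: real databases, real sequence
composition biases and real inter-operon variation are absent, so a
pipeline passing on fixtures is exercised, not validated, against real
communities.

## Scoring

### Confusion semantics and the singleton rule

At a fixed rank (family or genus), each read is scored against the taxon
of the genome it was extracted from: **TP** if the assignment projects
to the same rank-level taxon, **FP** if to a different one, **FN** if
the read was discarded by the pipeline or is unclassified (including
"classified, but above the evaluated rank" — an order-level call carries
no information at family level, so it is unclassified-at-rank). Then
`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and the F-measure is
their harmonic mean, with all zero-denominator cases defined as 0.
`TP + FP + FN` always equals the number of truth reads.

With `drop_singletons = TRUE` (the protocol's setting), taxa supported
by exactly one read are removed after rank projection and their reads
recounted as FN before TP/FP are tallied — mirroring clustering-first
pipelines' default removal of singleton OTUs, applied uniformly so
assignment-first pipelines are scored under the same rule. The filter is
per evaluation (rank × run), not global.

### Richness, diversity, taxonomic merging

`merge_otus()` performs the taxonomic-merging step: OTU sizes pool per
rank-projected taxon (unclassified OTUs into a reserved `"unclassified"`
key), making clustering-first and assignment-first outputs comparable
units. On the merged (or per-read) profiles, with the unclassified key
excluded:

* **Chao1** `= S_obs + f1(f1-1) / (2(f2+1))` — the bias-corrected form,
  matching the defaults of the common OTU pipelines; the classic
  `S_obs + f1^2/(2 f2)` form is available behind a flag. Its signed
  **error percent** against ground truth is
  `(estimate - truth)/truth * 100`, where "truth" is the number of
  distinct rank-level taxa among the dataset's truth reads (equal to the
  design's richness whenever every designed taxon amplified).
* **Shannon** `= -sum p_i ln p_i` (natural log, base configurable) and
  **Inverse Simpson** `= 1/sum p_i^2`, the effective number of equally
  abundant taxa.

### Partition agreement

The truth taxa and the predicted taxa at a rank are two partitions of
the same read set. From their contingency table we report
`NMI = I(U;V)/max(H(U),H(V))`, the chance-adjusted
`AMI = (I - E[I])/(max(H,H) - E[I])` with `E[I]` the exact
permutation-model (hypergeometric) expectation, and `1-NID`. The **max
normalization** was chosen deliberately: under it `1-NID` and NMI
coincide, so one contingency computation serves both and the two
reported numbers cannot disagree about direction. Unclassified reads
enter the predicted partition as one dedicated cluster — they must
penalize agreement, since heavy unclassified fractions are precisely
what degrades rank-level interpretability — while discarded reads are
excluded from both partitions (configurable assumptions, stated here
because published index definitions often leave them implicit).
Degenerate conventions: both sides single-cluster scores 1; one side
single-cluster scores 0; negative AMI clamps to 0.

The test suite checks all three metrics against brute-force oracles —
loop-based entropy computation, and `E[I]` by full enumeration of label
permutations — exhaustively over every pair of set partitions of up to 6
items.

## Cross-pipeline comparison

`build_profile_matrix()` stacks per-pipeline family profiles (union of
taxa as columns), drops the unclassified key and renormalizes rows —
comparisons operate on relative abundances of classified reads, with a
raw-count mode behind a flag. On that matrix:

* `euclidean_upgma()` — average-linkage clustering on Euclidean
  distances; rows are pre-sorted by label so ties break deterministically
  and the result is invariant to input order. The newick export encodes
  merge heights ultrametrically (leaf depth = merge height / 2, so
  cophenetic distances reproduce the merge heights).
* `bray_curtis_matrix()` + `pcoa()` — classical scaling of the
  Bray-Curtis matrix; negative eigenvalues (Bray-Curtis is
  non-Euclidean) are dropped, not corrected, and reported so the
  distortion can be judged.
* `rank_sum_test()` — two-sided Mann-Whitney-Wilcoxon between pipeline
  groups (e.g. clustering-first vs assignment-first richness estimates).
  The exact null is enumerated when the combined n is at most 12 with no
  ties — full enumeration is cheap at the group sizes pipeline
  comparisons involve — otherwise the tie-corrected,
  continuity-corrected normal approximation applies. Two-sided is the
  default because a benchmark has no a-priori direction.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; truth-table TSV exports
  are 1-based inclusive with a header line saying so.
* Name-based assignments resolve by exact, case-insensitive scientific
  name; ambiguous names resolve to the shallowest node with a warning,
  and `strict = TRUE` turns unresolvable names into errors. Divergent
  database nomenclatures are a real reconciliation problem with no
  universal answer, so the package exposes the strict/lenient switch
  rather than guessing.
* Retired taxids remap through optional `merged.dmp` support.
* All zero-denominator conventions (F-measure, degenerate partitions)
  are defined as 0 and noted in the function documentation.

## Problem sizes used in the checks

The shipped verification uses 50,000-read simulations from 200 nt and
400 nt amplicons for error-model recovery (3 binomial-SE bands; 5%
relative on length SD), 25,000-read datasets for composition recovery
(exact), exhaustive partition enumeration to n = 6 for the information
metrics, and 12-genome fixture collections (3 families × 2 genera × 2
species, 1–3 marker copies) for end-to-end identity: a truth-copying
pipeline scores F = 1, Chao1 error 0% and 1-NID = 1 at family and genus,
and an all-unclassified pipeline scores recall 0. These sizes give
stable stochastic checks while keeping a full run in minutes on one
core.

## Known limitations

* Fixture realism: synthetic markers have no homopolymer structure, no
  intra-genome operon divergence, no database mismatch — the hard parts
  of real classification. The package measures pipelines' behaviour on
  controlled inputs; it does not certify real-data accuracy.
* The error model is a declared simplification (global rates, linear
  positional ramp, no homopolymer coupling).
* The name resolver is exact-match only; taxonomies with heavy synonymy
  need a pre-mapping step.
* Mann-Whitney exact enumeration is limited to small tie-free groups by
  design; larger comparisons use the normal approximation.
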