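---
title: "Models and methods behind karyograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyograph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyograph)
```

karyograph packages the comparative-genomics computations used to study
chromosome evolution in chromosome-scale assemblies: reconstruction of
ancestral linkage groups (ALGs), macro- and microsynteny, ultraconserved
element detection, Hi-C insulation boundary statistics, and the scaling
of regulatory-element-to-gene distances with genome size. This vignette
explains each model, its assumptions, the tunable parameters, what the
synthetic-data generators emulate, and the numerical decisions taken
where the design was genuinely open.

## Coordinates and input formats

All internal coordinates are 0-based half-open. BED is consumed
natively; GFF3 `gene` features are converted on read (1-based closed to
0-based half-open) and reconverted on write, so the round trip is the
identity. Gene order within a chromosome is by start coordinate, ties
broken by (end, gene id); the resulting 0-based rank (`ordinal`) is the
position used in all synteny computations. Strand is recorded but never
used by the synteny machinery — none of the implemented analyses
condition on orientation, and inversions are invisible to them by
design. Species assembled only to scaffolds are handled by treating
every sequence as a "chromosome".

## The karyotype evolution simulator

`simulate_clade()` evolves an ancestral karyotype (default 18
chromosomes of 150 single-copy genes) down a species tree. Per branch,
event counts are Poisson(rate x branch length) for six event types:
chromosome fusion (end-to-end join of two uniform chromosomes, order
recorded), fission (uniform gene-boundary cut), reciprocal
translocation (suffix exchange at uniform cut points), intra-
chromosomal transposition (one uniform gene to a uniform position on
its own chromosome), gene loss and gene duplication. Every extant gene
carries its ancestral gene id, so the simulator emits exact ground
truth: the true ALG of every orthogroup, a truth orthology table, and
an event log that replays deterministically (`replay_event_log()`);
replay identity is asserted in the test suite. All randomness derives
from one root seed via labelled stream hashing (`derive_seed()`), so
adding an event type or consumer does not perturb existing draws.

Default rates are 2 fusions, 2 fissions and 100 transpositions expected
per branch with translocation, loss and duplication off — a regime in
which gene order decays quickly (as observed between anemone genomes
that diverged ~174 My ago) while gene-to-chromosome assignment stays
informative. Real rearrangement rates are poorly quantified; these
defaults are calibration settings for recoverability studies, not
estimates.

**The default tree is a six-leaf star** (hard polytomy, unit branch
lengths). This is a deliberate design choice, not a simplification of
convenience. On a deep balanced tree, a fusion on an internal branch is
inherited by every descendant leaf; with edge weights defined as
supporting-species counts, two ALGs fused in even two of six leaves are
connected by a complete bipartite block of weight-2 edges, and merging
them becomes the modularity-optimal partition at the scenario the sweep
selects. That is correct behaviour — the fusion genuinely is a shared
derived feature of the data — but it means the true ancestral karyotype
is only identifiable when most rearrangements are lineage-private. The
star default puts the generator in that identifiable regime; arbitrary
newick trees (including deep ones) are accepted, with the caveat that
shared-derived fusions will be reported as merged ALGs. A related
intrinsic limit: with small karyotypes the same fusion arises
independently in two lineages by chance (a birthday-paradox collision
over chromosome pairs), which is indistinguishable from a shared
fusion; at 18 chromosomes and 12 fusions per clade the expected number
of collisions is ~0.4, at 8 chromosomes it exceeds 2.

The other generators are: `generate_contact_map()` — expected contact
`c0 (1+s)^(-alpha)` at bin distance `s`, optional within-block
enrichment between listed boundaries, mean-corrected multiplicative
log-normal noise; `plant_conserved_alignments()` — gap-free HSP pairs
with per-column background match probability and planted 100%-identity
segments; `generate_atac_dataset()` — peaks at signed Exp(mean) offsets
from uniform gene boundaries, resampled until disjoint from all genes.
The planted-alignment generator forces a 3-column mismatch guard band
around each element so that the planted span coincides with the maximal
high-identity interval; without the guard, an adjacent background column
that matches by chance genuinely belongs to the conserved run and
"exact" truth boundaries would be ill-posed.

What the generators do **not** emulate: nucleotide-level evolution
(alignments are synthetic match/mismatch columns, no indel process in
the generator), whole-genome duplication, inversions, assembly error,
annotation noise, or mappability/coverage artefacts in Hi-C and ATAC
data. Passing tests therefore demonstrate the correctness and
statistical behaviour of the algorithms under the stated generative
models, not robustness to every artefact of real data.

## Ancestral linkage group inference

`place_orthogroups()` assigns each orthogroup, per species, to the
chromosome holding a strict plurality of its member genes (ties ->
unplaced). `build_linkage_graph()` joins two orthogroups with weight
`w` = number of species in which they are co-resident; edges with
`w < min_support` (default 2) are dropped so that every edge reflects
cross-species agreement — single-lineage fusions cannot link ALGs.

Communities are found by consensus clustering: `n_runs` Leiden
optimizations of weighted modularity at the given resolution (distinct
derived seeds), a co-assignment frequency matrix thresholded at 0.5
(Lancichinetti–Fortunato), and re-application of the procedure on the
consensus graph until all runs agree. Two safeguards matter
numerically. First, the reported stability is the mean pairwise
run-agreement over node pairs in the first round. Second, the converged
consensus is compared with the best first-round run under the same
resolution-scaled objective and the better of the two is returned: on
small graphs the co-assignment majority can settle on a worse local
optimum than an individual run, and the floor restores the guarantee
that consensus never degrades the best solution found. With 20 runs
this attains the exhaustively enumerated modularity optimum on all
random graphs of up to 8 nodes in the test suite.

`scenario_sweep()` evaluates a resolution grid (default 0.5, 1, 2) and
selects the scenario with the highest plain (resolution-1) modularity,
ties toward fewer ALGs. Communities smaller than 1% of nodes are kept
in the assignment but excluded from the headline ALG count, mirroring
the practice of counting only major linkage groups. Modularity is
computed in-package (`modularity_score()`) and cross-checked against
igraph's implementation in the tests.

Problem sizes: the recovery studies in the tests and acceptance script
use 6-leaf clades of 18 x 150 = 2700 orthogroups with 10 Leiden runs
per scenario and grid {0.5, 1, 2}; one sweep takes ~15 s on one CPU.
These sizes were chosen so a full multi-seed study stays comfortable on
a laptop while the graph (~300k weighted edges) is large enough for the
consensus behaviour to be representative.

## Macrosynteny

`oxford_table()` uses single-copy orthogroups by default; multi-copy
groups are expanded to all cross products only on request, because
paralog cross products otherwise dominate dot plots.
`chromosome_correspondence()` deliberately uses descriptive joint
thresholds (count >= 5 and >= 5% of the chromosome's orthologs) rather
than a hypergeometric test: correspondences of interest here are gross
(hundreds of shared genes), a formal test adds only false precision at
small counts, and the thresholds are configurable. The defaults produce
no spurious partner on uniform random scatter at realistic sizes
(~8000 orthologs over 15 x 15 chromosomes). `project_algs()` calls a
fusion when two or more ALGs each hold >= 10 orthogroups and >= 10% of
a chromosome, and a fission when one ALG does so on two or more
chromosomes. `ancestor_mapping()` weights edges by the fraction of the
parent ALG's orthogroups found in each child group and flags weights
strictly above 0.8 as near one-to-one.

## Microsynteny

A block is a chain of orthologous gene pairs: strictly increasing
ordinals in species A, strictly monotone (either direction) in B, and
at most `max_intervening` interleaved genes between consecutive members
in each species, counted independently per species; a gene whose
orthogroup is missing from the partner species still counts as
intervening. Blocks are extracted greedily longest-first with full
determinism: among equal-length chains the lexicographically smallest
(ordinal-A, ordinal-B) sequence wins, then increasing direction. Every
gene instance is used at most once, so no reported block is extendable
with unused genes. The forward dynamic programme that finds each best
chain is verified in the tests against an independent exhaustive
depth-first enumeration on hundreds of random genome pairs.

Two subtleties. Counting blocks of length >= k from a single extraction
equals running the extraction with `min_len = k`, because longer blocks
are always extracted first — so counts are monotone in `min_len` by
construction. Counts are **not** monotone in the intervening budget: a
wider budget can merge two blocks of one instance into a single longer
one (the canonical 4-gene example: two 2-blocks at budget 0 become one
4-block at budget 1), so only the aggregate census, not each instance,
grows with the budget. Paralog filtering removes blocks whose most
frequent orthogroup occurs at least twice and makes up at least half
the members; requiring the duplicate keeps legitimate 2-gene blocks of
two distinct orthogroups, which a bare 50% rule would destroy.

## Ultraconserved elements

`window_scan()` seeds at every alignment window (default 20 columns)
with identity >= `min_identity` (default 0.95; gap columns are
mismatches), extends each seed rightward while the cumulative identity
of the growing interval stays at the threshold, trims each survivor to
start and end on matching columns, and merges overlapping survivors
(a merge that would drop the union below the threshold keeps the longer
survivor). The trimming step is essential: a maximal interval under the
bare identity criterion may begin or end with mismatches (25 matches
plus one trailing mismatch is still 96% identity), which would both
misplace boundaries and admit elements that fail re-validation.
Reported identities are recomputed from the raw aligned strings, and
the suite asserts that every element re-validates at >= 95%.

Column spans are mapped to genome coordinates by cumulative non-gap
counts; minus-strand subject hits map from the interval end.
Multi-mapping elements (query loci overlapping >= 50% of the shorter
span, single linkage) reduce to the pair with the largest summed length
in both genomes. Classification removes elements mostly (> 50%)
covered by CDS and labels the rest intronic or non-coding; recurrence
clustering links elements when a self-hit covers >= 90% of either
sequence. The upstream alignment step (discontiguous megablast with
template length 16, e-value 1e-10, repeat-masked genomes) is outside
the package; its tabular output with `qseq`/`sseq` columns is the
expected input.

At 95% identity and window 20, short chance elements are expected in
long alignments of ~70% background identity (a 20-column window passes
with probability ~0.8%), so planted-element studies assert exact
recovery of the planted spans and universal re-validation, not the
absence of short background survivors; zero-background assertions are
made at 50% background identity where the chance rate is negligible.

## Insulation and boundary strength

`insulation_track()` uses the square-window (Crane-style) score:
`raw(i)` is the mean contact of the `w x w` square pairing the `w` bins
left of `i` with the `w` bins right of it, excluding bin `i` itself;
the reported score is `log2(raw / mean(raw))` over defined bins, which
makes the track invariant to global scaling and mean-centred in ratio
space. The window default of 10 bins corresponds to 1 Mb at the 100 kb
bin size typical of these analyses; bins within `w` of a chromosome end
or with all-zero squares are undefined and are skipped, never
zero-filled. `call_extrema()` finds local extrema over defined bins
(endpoints excluded, plateaus collapsed to their centre bin) and
filters by topographic prominence (default 0.1 in log2 units — about a
7% contact change — to suppress noise wiggles). Boundary strength is
the mean of the drops from a valley to its nearest flanking peak on
each side (the `min` variant is available; the mean is the default
because a boundary's two shoulders are both informative), and valleys
with no flanking peak are dropped.

`compare_boundary_strength()` reports the U statistic and a two-sided
p-value: by complete enumeration of pooled-value assignments (midranks,
so ties are handled exactly) when `choose(n+m, n)` is at most 20 000 —
which covers all sample sizes where exhaustive verification is feasible
— and otherwise by normal approximation with tie and continuity
corrections, cross-checked against `stats::wilcox.test`. Literal
enumeration at larger sizes is combinatorially impossible, which is why
the branch point is the combination count rather than `n x m`.

`contact_decay()` regresses `log10 P(s)` on `log10(1 + s)` — the same
offset that keeps the power law finite at distance zero — so on a
noise-free `c (1+s)^(-a)` matrix the fitted slope is exactly `-a`;
regressing on `log10 s` instead would bias the slope upward by ~0.11
over distances 1–50. No TAD caller is provided, intentionally: the
scientific claim these tools support is about the *absence* of strong
boundaries, which is quantified by boundary-strength distributions, not
by the output of a domain segmentation heuristic.

## ATAC peak-to-gene distances

Distances are measured edge-to-edge (peak boundary to the nearest gene
start or end on the same chromosome), after removing peaks that overlap
repeats, overlap or directly abut genes (abutting peaks have distance 0
and are excluded with the overlaps, keeping all distances >= 1), or lie
on gene-free chromosomes. Outliers beyond 1.5 x IQR from the quartiles
(type-7 linear interpolation, R's default) are removed before plotting
and regression. The regression is ordinary least squares of per-species
mean distance on genome size (sum of chromosome lengths, overridable)
with a pointwise 95% confidence band and Pearson r.

One statistical caveat is documented rather than hidden: for an
exponential distance law, the IQR filter always clips the upper tail
and shrinks every species mean by the same factor (~0.82), so the
filtered regression estimates an attenuated slope. Recovery studies of
the generative slope therefore run `size_regression(apply_iqr = FALSE)`;
the default keeps the filter on, matching the published procedure for
real data, where the filter targets artefactual extremes rather than a
clean parametric tail.

## Pipeline and reproducibility

`validate_config()` reads YAML, rejects unknown keys anywhere with one
aggregated report, checks referenced paths, and fills stage defaults;
`kg_main()` dispatches the subcommands (`simulate`, `rbh`, `alg`,
`macro`, `micro`, `uce`, `topology`, `atacdist`, `all`) and writes the
effective config next to the outputs. All writers emit deterministic
ordering, and every source of randomness flows through
`derive_seed(root_seed, labels...)`, so identical config and seed give
byte-identical outputs — a property asserted end-to-end in the tests.

## Known limitations

- Shared-derived fusions on internal tree branches are reported as
  merged ALGs; this is faithful to the data but means deep-tree
  simulations do not recover the ancestral karyotype exactly.
- The microsynteny chainer is greedy; it maximizes each successive
  block, not a global objective over all blocks, matching common
  practice but without global optimality guarantees.
- The UCE scanner's window length and extension rule are one reasonable
  concretization of a sliding-window-at-95% criterion; published
  element counts from other implementations need not match exactly.
- Contact matrices are consumed as text (COO or dense) per chromosome;
  binary cooler files must be exported upstream.
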