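---
title: "Inferring chromosomal rearrangements from single-gene FISH marker order"
author: "karyoCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromosomal rearrangements from single-gene FISH marker order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoCR)
```

## The data modality and its consequences

Single-gene FISH resolves, for each mitotic chromosome, which gene probes
hybridize where: an ordered list of marker sites, each on the short (S) or
long (L) arm, with a visible centromere between them. Three properties of
this modality fix the package's modelling choices:

* **Order, not distance.** Optical measurement of signal positions on
  condensed chromosomes is too noisy to treat as a metric. Positions are
  stored as fractions of chromosome length in [0, 1] from the short-arm
  telomere, but every inference consumes only their rank order and their
  side of the centromere.
* **No orientation.** A FISH signal says where a gene is, not which way it
  points. Sequences are therefore *unsigned* permutations, and the
  signed-permutation (Hannenhalli–Pevzner) machinery does not apply.
* **The centromere is an observation.** Arm membership is directly seen,
  so the centromere participates as an explicit token in the sequence.
  Whether an inversion moved the token is exactly what distinguishes a
  pericentric from a paracentric event, so reversal intervals may include
  the token, while breakpoint counting ignores it (the token breaks no
  gene adjacency).

Coordinates are 0-based with half-open intervals throughout, which keeps
reversal arithmetic uniform.

## From map to permutation

`buildPermutation()` separates an observed chromosome into four channels
before any rearrangement logic runs:

1. own-group, single-copy sites → the unsigned permutation;
2. maximal runs of foreign-group sites, flagged terminal or interstitial →
   the translocation/duplication channel;
3. reference probes absent from the map → missing (the reference index set
   shrinks and is re-ranked densely, so the sequence is always a
   permutation of 0..n−1);
4. repeat occurrences of an already-placed probe → extra copies.

This mirrors how such maps are read in practice: inversions from own-group
probe order, translocations from cross-group signals, and copy-number
events from site counts — three nearly orthogonal signals.

## Minimal inversion scenarios

`minInversionScenarios()` searches all reversals of contiguous intervals
(≥ 2 elements of the token-inclusive sequence) transforming the reference
into the observed order, and returns *every* scenario of minimal length.
Retaining the full set is deliberate: cytogenetic narratives often assert
one multi-step history where several equally short ones exist, and forcing
a single history would overstate certainty. The lexicographically first
(canonical) scenario names events deterministically; comparative logic
treats scenario sets.

Mechanics and numerical choices:

* States are relabelled once so the observed marker order becomes the
  identity; breakpoints of any intermediate state are then breakpoints
  relative to the target, and reversal intervals are positional and
  unaffected.
* The search prunes on the provable bound d ≥ ⌈b/2⌉ (one reversal heals at
  most two breakpoints) and solves the final step constructively: with
  distinct elements, the reversal mapping one state to another is unique
  when it exists.
* `maxDepth` defaults to 4: the deepest narrated series in the motivating
  surveys is three successive inversions, chromosomes carry 7–10 markers,
  and exhaustive unsigned search beyond depth 4 at n = 12 stops being a
  desk-scale computation. Deeper distances return `Inf` with an empty
  scenario set rather than a silently truncated answer.
* Sequences longer than 12 markers are rejected outright; this package
  targets FISH-scale maps, not sequence-scale synteny blocks.

A step is classified pericentric iff its interval contains the centromere
token *at application time* — the token moves with earlier pericentric
steps, and classification respects that.

## Translocation and copy-number calls

`detectTranslocations()` pairs terminal foreign runs: a run on A sourced
from B's homoeologous group, matched by a run on B sourced from A's group,
is one reciprocal translocation (emitted once, chromosomes in lexicographic
order, same-subgenome partners preferred); unpaired runs are one-way
translocations attributed to the same-subgenome chromosome of the source
group. Two guard rules prevent cross-talk between channels: interstitial
foreign probes are never translocations (they are duplication candidates),
and a *single-probe* terminal foreign site only counts as a translocation
candidate if the probe's home site is vacant — otherwise its home is
intact and the extra site is a duplication.

`detectCopyNumber()` compares each probe's site count per subgenome with
its declared complement (1, or 2 for the multi-site probes): surplus sites
off the home chromosome are duplications; a probe absent from its home
chromosome *and from the whole subgenome* is a deletion only when its two
nearest reference neighbours are present there. The neighbour requirement
distinguishes deletion from a truncated or partially hybridized map, and
the subgenome-wide check keeps translocated probes from being double-called
as deletions. Multi-site probes are represented as a single manifest row
with an expected complement of two sites, rather than as rows in two
reference orders — placing the second site into another group's reference
would make every karyotype expect it there, which is wrong for a site that
is itself a duplication in some lineages.

## Species-level accounting

Two counting units coexist, on purpose:

* **Complexes** for species-specificity: all inversions on one chromosome
  in one material are one rearrangement (a multiple-inversion series is a
  single evolutionary accident until proven otherwise), and RT partner
  rows merge. A complex is species-specific for X iff its signature is
  identical in every material of X and not uniformly identical in the
  other *Elymus* species; this automatically excludes non-uniform series
  (e.g. chromosomes whose inversion load differs between materials).
  The diploid H-genome outgroup is excluded from the comparison — a
  rearrangement shared with the progenitor can still be species-specific
  among the polyploids, and the ancestral-state annotation is carried
  separately in the fixture rather than used as a veto.
* **Raw event types** (chromosome + label, translocation partner rows
  merged) for polymorphism counts, which is how the survey tables
  enumerate polymorphic CRs — including co-located distinct events on one
  chromosome that a complex would merge.

`breakpointReuse()` deduplicates identical shared complexes within a
species (shared = inherited once) but counts like-for-like complexes in
different species separately (independent origins are exactly what
breakpoint *reuse* means).

## The simulator, and what passing tests do not show

`simulateKaryotype()` starts from identity chromosomes over a reference and
applies explicit inversions, reciprocal/one-way terminal translocations,
duplications and deletions, then re-spaces positions uniformly within each
arm (order is all the inference consumes, so uniform spacing loses
nothing). Defaults emulate the study conditions: 7–10 markers per group
(default 8), three subgenomes St/H/Y with the species' complement, a
centromere at 0.45 of chromosome length (a typical submetacentric ratio),
and the observed event taxonomy. `sampleDisjointInversions()` draws
inversions with ≥ 2 markers and pairwise-separated intervals, so each
reversal contributes two fresh breakpoints and the true minimal scenario
length equals the number applied — giving the recovery tests an exact,
provable target. Overlapping inversions are deliberately outside the
sampled space: overlapping reversals can compose into fewer steps, so for
them only d ≤ k and map reproduction are meaningful assertions.

The simulator emulates marker order, arm membership and copy number. It
does not emulate hybridization failure, signal-intensity ambiguity,
near-centromere arm uncertainty, or measurement noise in positions — so
green recovery tests certify the inference logic, not robustness to
imperfect cytology. Real maps with ambiguous near-centromere sites would
need both arm placements tried; the packaged demonstrations avoid that
regime.

## Packaged fixtures and problem sizes

The package ships the survey tables it accounts for: a 48-event × 11
material presence grid and a 10-material × 21-chromosome repeat-FISH
pattern grid, transcribed with material rows only — the printed summary
rows are recomputed by the tests, never copied. The probe manifest carries
the 59-probe complement (22 previously reported + 37 new, 4 discarded
candidates listed separately); probe names not given in the survey text
are synthetic placeholders at positions consistent with the narrated arms.
Exact per-chromosome marker orders live in supplementary material that is
not packaged, so the demonstration karyotypes (`demoKaryotype()`) are
prose-derived reconstructions built by the simulator: they reproduce the
narrated event lists and support demonstrations, not acceptance checks.
The group-4 breakpoint-reuse table is likewise figure-derived with
synthetic intervals arranged to reproduce the narrated four-fold reuse.

Test problem sizes: oracle agreement runs 500 random permutations of
n ≤ 8 markers against an independently written iterative-deepening search
(depth 4 for n ≤ 5, 3 at n = 6, 2 at n = 7–8); simulator recovery runs 200
replicates of 1–3 breakpoint-disjoint inversions on 8-marker chromosomes.
These sizes exercise every code path of the search at the marker densities
the method is designed for while keeping the whole suite under a minute.

## Known limitations

* Unsigned reversals only: transpositions and signed models are out of
  scope, matching what the data modality can support.
* The greedy probe-selection filter ("first eligible, then nearest to the
  previous pick plus 100 Mb, per chromosome") is the simplest
  deterministic reading of an "evenly spaced" prescription; other
  spacing objectives are defensible.
* One-way translocation sources are attributed to the same-subgenome
  chromosome of the source group; single-gene probes mark homoeologous
  groups, not subgenomes, so a cross-subgenome source is indistinguishable
  without repeat/GISH evidence.
* Reference intervals attached to inversion events are exact for the first
  step of a scenario and value-span approximations for later steps;
  breakpoint-reuse analyses on multi-step chromosomes should use curated
  intervals, as the packaged group-4 table does.
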