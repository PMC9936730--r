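# karyoCR

Comparative single-gene FISH karyotype analysis for Triticeae
allopolyploids: rearrangement inference from ordered marker maps,
species-specific vs. polymorphic classification across materials,
chromosome-variant accounting from repeat-FISH pattern tables, and
breakpoint-reuse quantification.

## The problem

Single-gene FISH places 7–10 gene probes per chromosome as an *ordered*
physical map — relative positions and arm membership, never base pairs or
orientation. Against a rearrangement-free reference collinearity standard
(the wheat D genome), disruptions of probe order reveal chromosomal
rearrangements (CRs): pericentric and paracentric inversions (PeI/PaI),
reciprocal and one-way translocations (RT/T), duplications (Du) and
deletions (De). In *Elymus* allopolyploids — *E. sibiricus* (StStHH) and
*E. nutans* (StStHHYY), with the diploid outgroup *Hordeum bogdanii* (HH) —
comparing these calls across materials separates rearrangements fixed in a
species from polymorphisms segregating within it, and comparing event
endpoints across lineages quantifies breakpoint reuse.

## The model

An observed chromosome is an **unsigned permutation** π of dense reference
ranks 0..n−1, with a distinguished centromere token ○ inserted at its
observed rank. Foreign-group marker runs are excised first (they carry the
translocation signal), missing probes shrink and densely re-rank the
reference, extra copies go to a duplication channel.

* **Breakpoints** b(π): reference adjacencies |i−j| = 1, framed by telomere
  sentinels, that are not adjacent in π (the token is ignored).
* **Minimal inversion scenarios**: exhaustive search over reversals of
  contiguous intervals of the token-inclusive sequence, from the reference
  to π, using the provable bound d ≥ ⌈b/2⌉ as a prune. All scenarios of
  minimal length are returned; a step is PeI iff its interval contains ○
  at application time, else PaI. The lexicographically first scenario names
  events; downstream logic keeps the whole set.
* **Complexes**: for species-level accounting, all inversions on one
  chromosome in one material collapse into one inversion series, and RT
  partner rows merge. A complex is *species-specific* for X iff identical
  in every material of X and not uniformly identical in the other species;
  *polymorphic* iff present in some but not all materials.
* **Breakpoint reuse**: a locus is the open interval between two
  reference-adjacent probes (or probe-to-telomere/centromere); its usage is
  the number of distinct complexes — shared complexes deduplicated within a
  species, counted separately across species as independent origins — with
  an interval endpoint there.

## Worked example

A demonstration *E. sibiricus* karyotype carrying the narrated DY-type
rearrangements (built by the simulator over the packaged reference):

```r
library(karyoCR)

d  <- demoKaryotype("DY")
cm <- getChromosome(d$karyotype, "4H")
formatIdiogram(cm)
#> 6H048 4H138 4H455 4H242 | 4H388 4H289 4H527 4H604 4L-6

p <- buildPermutation(cm, crReference()[["4"]], crProbeManifest())
p
#> Permutation 4H: 0 4 2 | 3 1 5 6 7  [1 foreign run(s)]  [missing: 4H055]
```

The terminal `6H048` run is the 4H/6H reciprocal-translocation signal
(`4H055` sits on 6H in exchange); the residual own-group permutation needs
two pericentric inversions:

```r
p@foreignRuns <- data.frame()   # excised; inferEvents() does this itself
minInversionScenarios(p)$scenarios[[1]]
#>   start end classification
#> 1     1   6            PeI
#> 2     2   5            PeI
```

Survey-level accounting on the packaged tables:

```r
em    <- crEventSurvey()
calls <- classifySpecificity(buildComplexes(em), speciesOf(em))
countSpeciesSpecific(calls, "E_sibiricus")   # 8
countSpeciesSpecific(calls, "E_nutans")      # 5
countPolymorphicTypes(em, "E_nutans")        # 15

countVariants(crPatternSurvey(), "E_nutans")$perGenome
#>  H St  Y
#> 20 21 25

head(breakpointReuse(crGroup4Demo(), crReference())[, 1:4], 3)
#>   group       locus count reused
#> 1     4 4H138|4H289     4   TRUE
#> 2     4 4H455|4H527     2   TRUE
#> 3     4   4H242|CEN     1  FALSE
```

Eight species-specific CR complexes in *E. sibiricus*, five in
*E. nutans*; fifteen polymorphic CR types in *E. nutans*; 66 chromosome
variants in *E. nutans* (20 H + 21 St + 25 Y); and the group-4 short-arm
locus between probes 4H138 and 4H289 maximally reused (four independent
complexes).

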