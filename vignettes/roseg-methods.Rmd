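---
title: "Methods: descriptor matching, assay statistics and the synthetic world"
author: "roseg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor matching, assay statistics and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roseg)
```

## The model

A ROSE-G element is a terminal 5′-UTR hairpin in which a conserved CUGCU
core is paired, imperfectly, across the Shine-Dalgarno (SD) sequence. Two
single-base bulges face each other: the G of the core (element `s2` in the
descriptor layout) and a G on the SD-side strand (`s4`). At low
temperature the hairpin sequesters the SD; warming melts the weakly paired
core region and frees the SD for ribosome binding. The package treats this
motif operationally, through three lenses:

1. a *descriptor* — a fixed-length structural pattern over single strands
   and helices, matched exactly against genomic sequence;
2. a *reporter statistic* — the heat induction factor, the ratio of mean
   β-galactosidase activity at an elevated temperature to the activity at
   25 °C;
3. a *probing statistic* — control-normalized in-line cleavage
   intensities, contrasting wild-type against a stabilized mutant.

## The descriptor dialect and its semantics

A descriptor is a structure map (`s1 h1 s2 h2 s3 h2' s4 h1' s5`; a primed
reference is the 3′ strand of its helix) followed by one definition per
element: strands are `<id> <mismatch> <pattern>`, helices
`<id> <mismatch:insertion> <pattern5>:<pattern3>`. Patterns use the IUPAC
degenerate codes plus `*`. Decisions baked into the implementation:

* **Fixed-length subset.** Both shipped search descriptors use equal-length
  helix strands and `0:0` allowances. Insertion allowances are rejected at
  parse time: supporting them would exceed what any shipped pattern
  exercises, and a fixed window makes the scanner, the analytic
  false-positive model and the brute-force oracle exactly comparable.
* **Antiparallel pairing.** Both helix strand patterns are written 5′→3′
  and position *i* of the 5′ strand pairs position *L−1−i* of the 3′
  strand. This is the only reading under which the SD-side strand pattern
  (`RG****`, a purine-rich block) lines up with the core-side pattern.
* **Pairing rules.** The default admissible pair set is Watson-Crick plus
  G·U wobble. The original search tool's pairing matrix is not documented
  in our sources, but the validated stem of the reference construct
  contains U·G pairs, so a strict-WC default would silently reject
  biologically validated geometry. Strict WC is available
  (`pairing_rules(wobble = FALSE)`) and the scanner's behaviour under both
  is property-tested. Mismatch allowances relax only *sequence-pattern*
  violations, never pairing.
* **`*` vs `N`.** Semantically identical (any base); kept distinct in
  parsing so descriptors round-trip byte-for-byte.
* **T → U.** Input sequences and descriptors are silently normalized to
  the RNA alphabet; `N` in a *sequence* matches only unconstrained pattern
  positions and never forms a pair (conservative).
* **Coordinates.** 0-based half-open everywhere internally and in BED;
  GFF3 is converted at the boundary (1-based, fully closed).

The scanner compiles a descriptor into flat per-position constraint tables
and evaluates every window with vectorized lookups; an independent,
deliberately naive per-window oracle in the test suite must agree exactly
on both shipped descriptors over ≥10⁴ random and planted sequences.

## Classification

The 5-nt core is read as the last two bases of h1's 5′ strand, the bulge
s2, and the first two bases of h2's 5′ strand. A hit is `ROSE_G` iff the
core is exactly `CUGCU` *and* s4 is `G` (the opposing bulged G); anything
else — including the ROSE-like `U(U/C)GCU` consensus — is `RELAXED`. The
restrictive descriptor constrains h1 to end in `CU` and s4 to `G`, but its
h2 begins `NU`, and the `N` pairs the SD-side `G`; under wobble rules that
position can therefore be `C` *or* `U`, so even restrictive-descriptor
hits split into `CUGCU` (ROSE_G) and `CUGUU` (RELAXED). The synthetic
generator records the truth class per planted instance for exactly this
reason.

## Candidate annotation

Both descriptors end in `NNAUG`: the hit carries its own start codon.
`annotate_candidates()` therefore defaults to `max_offset = 0` — a
candidate is kept only when a same-strand annotated CDS start coincides
with the descriptor's terminal AUG. A nonzero window is available because
annotation start codons occasionally disagree with descriptor placement.
Matches on sequences with no same-strand gene are retained and flagged
rather than dropped (they are still descriptor hits); matches whose
nearest gene lies beyond the window are dropped as unsupported. Duplicate
hits (same sequence, strand and span — e.g. from iterative searches with
overlapping descriptors) are collapsed.

## Structure tools

`to_dot_bracket()` derives the descriptor-implied structure: helices
bracketed, strands dotted. Named regions are attached as 0-based position
sets: `P2` (all helix positions), `L2` (the apical loop = element s3),
`SD_side` (h2′ through h1′, including the bulged s4) and `ROSEG_core`
(the 5-nt core). Two open points were resolved as follows:

* The descriptor's loop element s3 is 7 nt, while the reference
  construct's apical loop is described as a tetraloop (CCCU) — the extra
  positions being closing-pair-adjacent unpaired bases. We define `L2` as
  the full s3 span because the descriptor, not any particular construct,
  is the package's unit of structure; users probing a specific construct
  supply their own region map.
* Mutation coordinates (`G32C`, `U36C`, `ΔU36`, also spelled `dU36`) are
  interpreted on the *user-supplied construct sequence*, 1-based, with the
  reference base checked at application time. The library never hard-codes
  construct numbering: published mutant names are tied to a full-length
  construct whose sequence lives in supplementary material, and guessing
  an offset would corrupt every downstream coordinate. A reference-base
  mismatch is an error (it signals the wrong construct), not a warning.

The structural effect of the stabilizing bulge mutation is expressed by
`close_bulges()`: a *local re-pairing check* — if the two opposing bulge
bases can pair under the rules (as after G→C on the motif side), the pair
is added and the bracket string updated. No thermodynamic folding is
attempted anywhere in the package; the descriptor-implied structure is the
model.

## Assay statistics

* **Miller units**: `1000 × A420 / (time_min × volume_ml × OD600)` — the
  A420-only variant, because the underlying protocol records no A550
  light-scattering correction. Users with corrected absorbances simply
  pass them as `a420`.
* **Heat induction factor**: the ratio of *group means* (elevated T over
  25 °C), matching the printed definition of dividing expression at the
  elevated temperature by expression at 25 °C — not the mean of
  per-replicate ratios (available via `mean_of_ratios = TRUE` for
  comparison). Activity is Miller units in vivo and raw A420 in vitro.
* **Dispersion**: first-order (delta-method) propagation of the two group
  means: `sd(f) = f·sqrt(sem_hi²/m_hi² + sem_lo²/m_lo²)`. Whether the
  original error bars are this quantity or the sd of per-replicate ratios
  is not stated in our sources; propagation of the ratio of means was
  chosen because it is the dispersion of the estimator actually reported.
* **Test**: two-tailed two-sample Student *t* on per-replicate activities,
  equal-variance by default (the named test), Welch via
  `var_equal = FALSE`. Degenerate dispersion-free groups (noiseless
  simulations) return t = 0, p = 1 when means agree rather than erroring.

All of these are scale-invariant (multiplying every activity by a
constant changes nothing), which the suite asserts.

## Probing quantification

`normalize_regions()` divides each region's mean intensity by the
*unweighted mean of the two control-region means* (the apical-loop region
and the two invariant reference positions). No formula is given in our
sources beyond "normalized to" the control regions; the unweighted mean
was chosen because the two controls have very different sizes and a
pooled-position mean would let the larger region dominate. The resulting
statistic is invariant to global lane scaling (gel loading), asserted in
the tests. `condition_contrast()` reports `N(mut)/N(wt)` per region;
ratios below 1 mean reduced cleavage — a stiffer backbone — in the mutant.
Band-to-position assignment (ladder registration, densitometry) is out of
scope: input is position-indexed intensity.

## The synthetic world

The generators state one fixed world; none of their defaults were tuned
against test outcomes.

* **Genome**: i.i.d. background with adjustable GC (default 0.5),
  default length 10⁵ nt, 5 planted instances on alternating strands. The
  i.i.d. model is deliberate: the analytic false-positive expectation
  (`match_probability()`, an exact per-window product honouring the joint
  pattern-and-pairing constraint on helix positions) assumes it, giving a
  closed-form calibration target. Real genomes have Markov structure,
  repeats and skewed codon usage; a green false-positive test establishes
  scanner correctness, not a genomic false-discovery rate.
* **Plants**: instances are sampled position-by-position from the
  descriptor (helix partners drawn jointly from pairs satisfying both
  patterns and the rules), optionally mutated, inserted as reverse
  complements on the minus strand, and each is annotated with a fake CDS
  starting at its terminal AUG. Truth classes are re-derived from the
  planted sequence itself.
* **Assays**: 3 replicates (the study's replicate structure), 10 %
  multiplicative lognormal noise (mean-one), default folds 2.0 at 37 °C
  and 4.1 at 42 °C — the latter the measured wild-type induction of the
  validated reference thermometer, the former a mid-range value (37 °C
  factors are construct-dependent and no single value is canonical).
  In vivo rows carry OD600/volume/time consistent with their A420 so
  Miller-unit computation reproduces the intended activity exactly.
* **Probing**: paired positions cleave at rate 1, unpaired at rate 3
  (a 3-fold flexibility enhancement, typical of in-line probing
  contrast), 10 % noise. The supplied structure is read as the 42 °C
  wild-type state: core and SD positions emit the unpaired rate in the
  wild-type lane and the paired rate in the stabilized-mutant lane;
  control regions are unpaired in both lanes, making them invariant by
  construction. What the generator does *not* emulate: partial melting
  gradients, band compression, ladder misalignment, duplicate-gel
  variation.

## Numerical choices and degenerate inputs

* Scanner and generators are deterministic given a seed; generator
  functions seed the RNG from their config so identical configs are
  byte-identical.
* Windows shorter than the descriptor, empty sequences and empty match
  sets flow through as empty results; invalid alphabet characters are
  errors.
* `match_probability()` requires zero mismatch allowances (with
  allowances the per-element joint distribution no longer factorizes over
  positions; rather than approximate, the function refuses).
* Ties in gene joining (two genes equidistant from the AUG) resolve to
  the first by `which.min` — stable because genes are processed in input
  order.
* The t-test's "essentially constant" failure mode is intercepted: groups
  with relative range below 1e-10 take the analytic degenerate branch.

## Known limitations

* Only the fixed-length descriptor subset is supported — no
  variable-length ranges, transformation matrices, or pseudoknots.
* No thermodynamic folding or melting-temperature prediction; structure
  claims are descriptor-implied only.
* The BLAST-based cross-validation workflow and taxonomy visualisations
  of the original analysis are out of scope, as is any NCBI access; the
  genome-scale species census is therefore replaced by the property-based
  acceptance criteria in `tests/testthat/test-acceptance.R`.
* Downstream-gene identity is carried as free text (`product`); there is
  no transporter-family classifier.
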