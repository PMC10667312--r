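---
title: "Modelling SCRaMbLE rearrangements in a disomic synthetic chromosome"
author: "ScrambleDisome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SCRaMbLE rearrangements in a disomic synthetic chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ScrambleDisome)
```

## The system being modelled

An Sc2.0 synthetic yeast chromosome carries a palindromic loxPsym site in
the 3′ UTR of every nonessential gene.  Inducing Cre recombinase (SCRaMbLE)
recombines pairs of these sites, producing deletions, inversions and tandem
duplications of the intervening segments, and — when two sites near opposite
telomeres recombine intramolecularly — a circular chromosome that has shed
both telomeric arms.  Carried out in a *disomic* background (one wild-type
and one synthetic copy of the chromosome), SCRaMbLE perturbs only the
synthetic copy, so the screen reads out how reducing the dosage of specific
chromosome content relieves the fitness burden of aneuploidy.

`ScrambleDisome` models this screen end to end:

1. a **segment map** of the loxPsym-partitioned chromosome
   (`syntheticSegmentMap()`, `loadSegmentMap()`);
2. a **rearrangement simulator** calibrated to the screen's headline
   statistics (`simulatePopulation()`);
3. **sequencing-style evidence** — per-segment depth, junction lists,
   PCRTag-like wild-type:synthetic read ratios (`generateEvidence()`);
4. **reconstruction**: copy-number estimation, Eulerian traversal of a
   segment-end adjacency graph, minimal-event decomposition
   (`estimateCopyNumbers()`, `inferStructures()`, `minEventDistance()`);
5. **fitness and association statistics** (`growthRecoveryRate()`,
   `doublingTime()`, `associationScan()`, `stabilityGenerations()`);
6. **dosage / environmental-stress-response (ESR) expression scoring**
   (`simulateExpression()`, `dosageSummary()`, `esrScore()`).

`runPipeline()` chains all stages deterministically from one seed.

## The reference map

The default map (`syntheticSegmentMap()`) partitions a 1,028,952-bp
chromosome into 40 loxPsym-delimited segments.  The true number of segments
on the real chromosome is not published, so 40 is a design choice: large
enough that events have room to land and small enough that exhaustive
checks stay cheap.  Segment lengths are drawn once from a fixed internal
seed, so the map is a deterministic design, not a random fixture.  One
small centromeric segment sits at 48% of the length with the selection
marker on the segment immediately to its right — the dual selection
(centromere + marker) is what forces every surviving SCRaMbLEd structure to
keep centromere-adjacent content.  A single 20-kb right-arm segment is
designated the causal region (the "del20K" analogue).

## The rearrangement simulator

Per strain, the simulator:

* circularizes first with probability 0.89 (the observed fraction of
  circular survivors).  The circularization junctions sit close to the two
  telomeres (geometric offsets, mean 1 segment), following the mechanism by
  which a single intramolecular event between telomere-proximal sites forms
  the circle;
* draws an event count from a zero-truncated negative binomial with mean
  4.42 (the observed mean events per strain) and dispersion `size = 2`,
  chosen so that the fraction of strains with ten or more events matches
  the observed long tail (about 8%);
* draws each event's type from the observed multinomial (deletion 0.622,
  inversion 0.292, duplication 0.086) and its junctions from a
  proximity-biased law: spans are geometric with mean one segment, with a
  6% long-range tail whose span is uniform.  Intramolecular Cre
  recombination strongly favours proximal site pairs, and this span law is
  also what keeps each event's junction footprint identifiable downstream
  (see *Calibration*, below);
* treats viability per event: a recombination product that has lost the
  centromere or the marker dies immediately and is never observed among
  selected strains, so such junction draws are redrawn.  (Rejecting whole
  strain trajectories instead would distort every calibrated statistic —
  the realized circular fraction falls to 0.74 and the deletion share of
  events to 0.43 — because rejection preferentially discards
  deletion-heavy, circular histories.)

Fitness follows a mass-action dosage model with a planted causal term:
latent growth recovery (percent) is
`beta0 + betaMass * (1 - retained) + betaRegion * [causal region deleted] + e`,
`e ~ N(0, noiseSd)`, clamped at a floor.  Defaults (`beta0 = 5`,
`betaMass = 50`, `betaRegion = 25`, `noiseSd = 8`) reproduce the observed
recovery range (roughly 5% to 80%) and the negative retention–recovery
correlation.  Colony diameters (200 per strain, CV 0.15) are drawn around
the implied mean so that `growthRecoveryRate()` can re-estimate recovery
from colonies, as the screen does.

The causal region is given a 4-fold recombination propensity by default
(`hotspotWeight`): the del20K analogue sits inside the screen's observed
right-arm deletion hotspot, and without the hotspot the region is deleted
in too few strains for a population-scale association scan to have power.

### The event-count interpretation

`meanEvents` is the mean of the *truncated* law (every SCRaMbLEd strain has
at least one event); `meanEvents = 0` is the unSCRaMbLEd control, and
values in (0, 1] are rejected as unrepresentable.

## Evidence and reconstruction

Evidence is segment-level by design: per-segment synthetic-specific depth
(`baseline x copies x recoveryFactor`, Poisson noise optional), the list of
oriented junction adjacencies with support counts, and PCRTag-style read
counts.  Circular molecules are recovered about three-fold less efficiently
during library preparation, so their depth is scaled by 1/3; the
copy-number caller re-estimates the per-copy unit from the centromere and
marker segments (always retained under selection), letting the bias
self-normalize.  Because an anchor segment can itself be duplicated, the
caller fits integer divisor hypotheses of the anchor unit by a short
fixed-point refinement and keeps the Poisson-likelihood-best solution,
lightly penalized by total copy number.  Two degenerate cases are worth
knowing about: a circular molecule in which *every* segment count is even
is depth-indistinguishable from its half (the caller resolves to the
fewest copies), and minimal circles observed at a third of a 100x baseline
are depth-limited, which caps noisy per-segment call accuracy near 98.5%
rather than 100%.

`inferStructures()` enumerates traversals of the segment-end adjacency
graph that use every present segment exactly its copy number of times and
every observed junction at least once, deduplicates by canonical form
(rotation/mirror-minimal words), and ranks candidates by event distance to
the reference.  On noise-free evidence the true structure is always among
the candidates and is unique whenever the traversal is unique.

`minEventDistance()` certifies minimality where it can: deletion-only
patterns have a closed form (one circularization plus one deletion per
maximal missing interior run, which is provably minimal); small words are
searched exhaustively (breadth-first over event space); everything else
gets a constructive greedy decomposition — cyclic tandem collapse,
near-tandem completion (re-inserting runs deleted from one copy of a
duplication), longest-repeat block transposition, breakpoint-greedy
sorting by reversals, missing-run deletions — whose event list always
replays on the reference to the observed canonical structure.  Where the
exhaustive search verifies that no shorter list exists, `isMinimal` is
`TRUE`.

## Calibration of the span law

The span law is the one place where the generator was calibrated against
the screen's *observable* statistics rather than fixed a priori.  Event
counting from final structures is parsimony-limited: overlapping deletions
merge into one gap, deletions adjacent to the circularization joint are
absorbed into the arc choice, and events erased by later deletions leave no
trace.  Under a long-range (uniform junction pair) span law these losses
are catastrophic — most deletion events get absorbed into the
circularization arc and the classified deletion share collapses to ~17%,
which no counting method could repair.  Under the proximal law the
footprint of nearly every event survives into the final structure, and the
classified mix lands on the observed 62/29/9 split (pooled deletion
fraction 58–63% across seeds at n = 219).  The residual 1–2 point deficit
against the applied mix is the irreducible parsimony loss from merged and
absorbed deletions.

## Fitness statistics

* `growthRecoveryRate()`: `(Si - Sr)/Sr x 100` on mean colony diameters
  (medians behind a flag); warns below the protocol's 200 colonies.
* `doublingTime()`: log10-transformed OD600, ordinary least-squares slope
  in every window of 7 consecutive readings, `DT = log10(2)/max slope`.
  Exact on pure exponentials; on logistic curves the early capacity
  shoulder biases the estimate by under 1% at the default carrying
  capacity (OD 2.0).  Because the rule takes a maximum over ~130 noisy
  windows, multiplicative noise biases DT slightly downward; at 2% noise
  about 93% of estimates land within 5% of truth.
* `associationScan()`: per-segment Welch two-sample t-test of recovery
  between deleted and retained groups (the screen does not name its test;
  Welch with Bonferroni is the documented default, with a seeded
  permutation option because colony sizes are skewed).  Segments without
  contrast are returned untested with a reason.  A *null* calibration run
  sets both `betaRegion` and `betaMass` to zero: the mass-action term is a
  genuine association between every deletion and fitness, not a null.
* `stabilityGenerations()`: `g = ln(target)/ln(1 - p)` plus a Monte Carlo
  lineage simulator; `p = 0` returns `Inf` ("never").

## Expression and ESR scoring

Counts are negative binomial with fixed dispersion (0.05) around per-gene
log-normal baselines; library sizes are matched by construction, so no
normalization pipeline is modelled.  Genes on segments retained in the
synthetic copy double their mean, except a fixed buffered subset (10%)
held at 1x.  iESR (~300) and rESR (~600) synthetic gene sets shift up/down
by `2^(2.5 x burden)` where burden is `1 - recovery/100`.

Up/down calls against the euploid reference use a dispersion-aware z-test
on the log count ratio at p < 0.001 (a Poisson-conditional binomial test
would be badly anticonservative at biological dispersion — measured 18%
false calls at dispersion 0.05 versus the nominal 0.1%).  Set enrichment
among the calls uses the exact hypergeometric tail with
Benjamini–Hochberg adjustment.  A reversal is reported when the disome
parent shows the signature (both fractions above the cutoffs, default 0.5)
and the strain falls below in *both* directions.  The buffered-gene
fraction is estimated per strain and, more reliably, pooled across
replicate strains by averaging log fold changes before thresholding (the
single-strain estimate is inflated by measurement noise).

## What the generator does and does not emulate

Passing tests demonstrate that the analysis stack recovers exactly what
the generator planted: structures from noise-free evidence, the event mix,
a causal region, ESR signatures.  Real data differ in ways the generator
deliberately omits: read-level artefacts (mappability, chimeric reads),
non-tandem duplications, inter-chromosomal rearrangements, variance in the
circular recovery factor, batch structure in expression, and biological
correlation between fitness and expression beyond the one-dimensional
burden variable.  Conclusions about the method's behaviour on real strains
should be drawn accordingly.

## Problem sizes and determinism

All simulations in tests and in the acceptance script run at the study's
scale (219 strains, 40 segments) or smaller; exhaustive oracles run on
6-segment maps where full enumeration is cheap.  Every stochastic function
takes a seed or inherits the caller's RNG stream; `runPipeline()` derives
all stage seeds from the single config seed, records no wall-clock fields
in the report, and therefore reproduces its report JSON byte for byte.
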