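---
title: "Modelling the fate of expanded CAG-repeat lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the fate of expanded CAG-repeat lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqsim)
library(dplyr)
```

## The question and the model

Dominant polyglutamine disorders such as spinocerebellar ataxia type 2
(SCA2, *ATXN2*) and type 3 (SCA3/MJD, *ATXN3*) are caused by expanded CAG
repeats. Meiotic instability tends to lengthen the repeat from parent to
child, longer repeats mean earlier ages at onset (AO), and earlier onset
cuts into the reproductive period — so successive anticipations should
eventually eliminate a lineage. Working against that are increased carrier
fitness and segregation distortion in favour of the expanded allele.
`polyqsim` simulates the tug-of-war between these forces, one lineage of a
*de novo* expansion at a time, and asks: for how many generations does the
lineage persist, and does it end in elimination, fixation, or neither?

Each generation applies a simplified allele-frequency recursion,

$$p' = p \cdot w \cdot \mathrm{antcoeff} \cdot 2k,$$

with `p` the frequency of the tracked allele, `w` the carriers' relative
fitness, `k` the segregation coefficient (0.5 is Mendelian), and
`antcoeff` an anticipation coefficient in [0, 1] that discounts
reproduction by how much of the fertile window (ages 12–50) remains before
symptom onset. The classical diploid recursion reduces to this form because
the expansion is rare (no homozygotes, the wild-type frequency is
essentially 1) and fully dominant. The simplification is deliberate: the
unreduced homozygote and mean-fitness terms are documented here but not
implemented.

Per transmission the engine (i) adds a Gaussian instability draw to the
repeat length, (ii) anticipates the AO by the repeat change times the
locus' AO-per-repeat regression coefficient, (iii) re-derives the regime —
*expanded* at or above the pathogenic threshold (inclusive; 34 repeats for
*ATXN2*, 51 for *ATXN3*), *normal* below it — and (iv) updates the
frequency with fitness and segregation draws from the regime the allele was
in when transmitted, applying the anticipation penalty only if the
*offspring's* allele is expanded. Repeat lengths are continuous reals:
the model tracks the lineage average, not a single molecule, and fixed
lineages can carry fractional mean repeats. A frequency of exactly 0 is
elimination. Frequency 1 is fixation, which is absorbing for the frequency
while repeat/AO dynamics continue; a fixed lineage whose AO later falls to
the bottom of the fertile window while expanded becomes extinct, and one
that survives to the horizon is held. Everything else at the horizon is
persisting.

## The anticipation coefficient

`antcoeff` is built from an age-specific fertility schedule: the area under
the (linearly interpolated) fertility curve over ages 12–50 is normalized
to 1, and the coefficient at a given AO is the cumulative fraction of that
area up to the AO, plus the observed fraction of children born after
parental onset (8% in SCA2 families, 8.3% in SCA3/MJD), clamped to 1. It is
exactly 0 for onset at or before age 12 and exactly 1 for onset at or after
age 50. **This closed form is a reconstruction**: the defining ingredients
(area normalization, the 0/1 boundary behaviour, the additive post-onset
fraction) are documented properties of the published coefficient, but the
original closed-form expression appeared only in supplementary material we
could not obtain, so the simplest additive-then-clamp composition is used
and flagged here. The alternative reading — scaling the age-specific rates
multiplicatively by the post-onset fraction — is indistinguishable after
normalization, which is why the additive form was chosen.

The packaged schedule is *synthetic*: a Gaussian bump on integer ages
12–50, peak at 30 years, spread 6 years
(`make_synthetic_schedule(30, 6)`), emulating the unimodal shape of the
EUROSTAT 2019 European female fertility curve with near-zero rates at both
window edges. Any real single-year-of-age schedule can be supplied as an
`age,rate` CSV. The ensemble statistics below are tolerant to the precise
shape because `antcoeff` saturates at both window edges; schedule shape
mostly moves fixation-related quantities.

```{r schedule}
s <- default_schedule()
anticipation_coefficient(s, c(12, 30, 45, 50), 0.08)
```

## How the age at onset tracks the repeat

The AO moves by `-delta_repeats * ao_slope` per transmission. Two readings
of the slope are implemented:

* `ao_model = "regression"` (default): the slope is the locus regression
  coefficient (1.877 y/repeat for *ATXN2*, 1.652 for *ATXN3*) applied as a
  constant, so the AO is a deterministic function of the cumulative repeat
  change, anchored at the ancestral (repeat, AO) pair. This matches the
  source study's presentation of AO as a function of repeat length through
  the regression, and it reproduces its fixation-time repeat statistics
  closely (for instance a mean repeat at fixation of ~64 in SCA3
  ensembles).
* `ao_model = "sampled"`: the slope is drawn per transmission from its
  mean/SD. This treats the printed slope dispersion as per-meiosis
  variation; it decouples AO from repeat length and widens the repeat
  range at elimination far beyond the published one, which is why it is
  not the default.

The slope is carried in both regimes (it is a locus property, not a regime
property), so a contraction raises the AO and a re-expanded allele re-enters
the pathogenic range with a plausibly late onset. While the allele is in the
normal range the anticipation penalty is exactly 1 — selection on the
disease phenotype does not act on an unexpanded allele — but AO bookkeeping
continues so that re-entry behaves sensibly. There is no upper AO cap;
`antcoeff` saturates at 1 above age 50 anyway.

## Parameters

The two presets carry literature means (SDs):

| | w | k | instability | AO slope (y/repeat) |
|---|---|---|---|---|
| *ATXN2* expanded | 1.50 (0.25) | 0.404 (0.085) | 2.42 (5.655) | 1.877 (1.86) |
| *ATXN3* expanded | 1.45 (0.25) | 0.640 (0.085) | 1.23 (5.126) | 1.652 (1.729) |
| *ATXN2* normal | 1.00 (0.25) | 0.596 (0.085) | 0.23 (0.468) | — |
| *ATXN3* normal | 1.00 (0.25) | 0.360 (0.085) | 0.00 (0.468) | — |

Several SDs are imputations inherited from the source meta-analyses rather
than observations: both fitness SDs (0.25, chosen to allow carrier and
non-carrier fitness to overlap), the SCA2 segregation SD (copied from
SCA3), and the SCA3 normal-allele instability SD (copied from the ATXN2
normal allele, whose mean of 0 is itself imputed). They are preset values
here, flagged in the documentation, and `sensitivity_sweep()` exists
precisely to vary the imputed fitness SDs (both regimes jointly by default,
per-regime via its `regimes` flag).

Run controls follow the source protocol: initial frequency $10^{-6}$,
ancestral state 34 repeats / AO 55 y (SCA2) and 54 repeats / AO 65 y
(SCA3), a 650-generation horizon (the published Methods value; the
abstract's "one thousand generations" is read as loose phrasing — the
horizon is configurable), and 1,000 lineages per ensemble.

Gaussian draws are untruncated on purpose: truncation rules are nowhere
documented, and a rare non-positive fitness or segregation draw simply
drives the frequency to 0, a legitimate elimination route (it is the only
way an unexpanded lineage can be eliminated, since its anticipation penalty
is 1). No underflow floor is imposed on frequencies; persisting lineages
reach values around $10^{-110}$ by generation 650, far above the smallest
positive double.

## Randomness and reproducibility

`run_ensemble()` seeds R's RNG with the master seed, draws one private seed
per lineage (`sample.int(2^31 - 2, n)`), and each lineage then consumes its
own stream — results are independent of execution order. Within a lineage
all `max_generations` draws for both regimes are generated up-front in a
fixed order (8 Gaussian vectors) and indexed by generation, so trajectories
are bitwise reproducible and the stream layout is documented enough to be
replayed independently (the test suite does exactly that). A run manifest
(`write_manifest()`) embeds the resolved configuration and the full
fertility table; replaying it reproduces output files byte-for-byte, helped
by all floating-point file output being rendered at 12 significant digits.

## Numerical choices and degenerate inputs

* The cumulative fertility fraction integrates the piecewise-linear rate
  curve exactly (piecewise-quadratic cumulative), rather than
  knot-trapezoid approximation, and clamps outside the window.
* Threshold comparisons are inclusive (`repeat >= threshold` is
  pathogenic) on continuous repeat values.
* Frequency clamps are exact: products at or below 0 become exactly 0,
  at or above 1 exactly 1, so elimination and fixation are crisp events.
* With all SDs zero the engine is deterministic and the elimination
  generation has the closed form
  `ceiling((ancestral_ao - 12) / (instability * slope))` — 10 generations
  for the SCA2 preset, 27 for SCA3; `zero_sds()` exposes this mean-path
  model, which the tests compare against the closed form over random
  parameter triples.
* An ensemble of `n = 1` works; empty strata (e.g. no fixations) are
  reported as absent, not zero. `summarize_outcomes()` refuses empty
  input.
* Ties at the fixation/elimination boundary inside a single step resolve
  in favour of elimination: if the anticipation coefficient is 0, the
  product is 0 regardless of the other draws.

## What the ensembles show

```{r ensembles, eval = FALSE}
sca2 <- run_ensemble("sca2", n = 1000, master_seed = 1)
sca3 <- run_ensemble("sca3", n = 1000, master_seed = 1)
sca2$summary
sca3$summary
compare_diseases(sca2, sca3)
```

At full scale (1,000 lineages, a few seconds per ensemble on one CPU) the
SCA2 preset eliminates essentially every lineage quickly — elimination
median around 12 generations — with a few dozen lineages fixing as
*contracted, non-pathogenic* alleles (median repeat at fixation ~32, below
the 34-repeat threshold) after roughly 90 generations; every fixed SCA2
lineage later re-expands and goes extinct. The SCA3 preset is qualitatively
different: only about two thirds of lineages are eliminated, fixation
happens early (~26 generations) at clearly expanded lengths (~64 repeats),
and roughly a quarter of lineages persist to generation 650 at vanishing
frequencies with repeats oscillating around the pathogenic boundary. The
directional contrasts — SCA2 eliminating more than SCA3, SCA3 persisting
substantially, SCA2 essentially never persisting — are stable across seeds
and across the fitness-SD sensitivity sweep, and are asserted as
invariants in the test suite.

Compared with the published simulation study these ensembles reproduce the
repeat-length statistics at fixation almost exactly and the fate counts
within the documented reconstruction slack, while fixation and elimination
*timing* medians sit several generations off (SCA2 fixation in particular:
~90 versus a published 60). Those quantities are the most sensitive to the
reconstructed anticipation coefficient; the acceptance tests state their
bands explicitly and the deviations are left visible rather than absorbed
into wider tolerances.

## What the synthetic generator does not capture

The packaged fertility schedule is a clean unimodal curve: it has no
cohort effects, no historical shift toward earlier childbearing (which the
source study itself flags as a limitation for 650-generation horizons), and
no male fertility schedule. The model excludes *de novo* mutation influx,
genetic drift, and gene flow by construction, tracks lineage means rather
than individual pedigrees, and treats fixation as absorbing for the
frequency. Passing tests therefore demonstrate internal consistency of this
model and agreement with the published ensemble behaviour — not predictions
about any particular family.

## Problem sizes used in the checks

The test suite runs its full-scale checks at the study's own scale
(1,000 lineages, 650 generations, five master seeds per disease for the
ensemble statistics; 4,000 lineages for a convergence check; $10^5$ draws
for distribution recovery). These are the sizes the package is meant to be
used at; a complete run of the suite takes a few minutes on one CPU.
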