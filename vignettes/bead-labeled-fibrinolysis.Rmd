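---
title: "Quantifying bead-labeled fibrinolysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bead-labeled fibrinolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadlysis)
```

Single fibrin fibers suspended across 20 µm ridge gaps are labeled with
20 nm fluorospheres and digested by plasmin while a time-lapse image is
captured every 30 s. Each fiber ends the hour in one of a small set of
fates — cleaved (at the ridge connection or along its length, with or
without further digestion) or uncleaved (tense, elongated, bundled, or
both) — and the rates of these fates depend strongly on the bead
concentration used for labeling. This vignette explains the models behind
each stage of the package and the choices made where the design was
genuinely open.

## Dosimetry

The bead number concentration follows the manufacturer's relation

$$ N/\mathrm{mL} = \frac{6\,C \times 10^{12}}{\rho\,\pi\,d^3}, $$

with $C$ the solids weight–volume fraction (0.02 for a 2 % stock), $\rho$
the material density in g/mL (1.05 for polystyrene) and $d$ the bead
diameter in µm (0.02). This gives a stock of
`r signif(beads_per_ul(beads_per_ml(bead_prep())), 3)` beads/µL. Because a
"dose" is more meaningful relative to the object being labeled, the
package also expresses concentrations as the expected bead count inside
one reference fiber cylinder (20 µm × 100 nm, ≈ 0.157 µm³): about 714 at
stock, 7.1 at the 1:100 dilution.

Full precision is kept internally everywhere; display rounding (3
significant figures for concentrations, 2 for beads per fiber volume)
happens only in reports. The 1:300 dose is 2.38 beads per fiber volume and
is displayed as 2.4.

Light dosimetry uses a default power of 170 µW — the midpoint of the
measured 160–180 µW range, and the single value consistent with both a
0.612 J continuous hour and a 0.00408 J gated hour. The default gated
schedule is one 200 ms exposure per 30 s frame over one hour (120
exposures), a 150-fold energy reduction.

## The lattice diffusion–binding model

A bead in the labeling solution performs a random walk on a
square lattice (Δx = 0.02 µm) inside a 2 µm × 2 µm box whose bottom row is
the fiber: reaching it binds the bead irreversibly (absorbing boundary).
The top, left and right walls reflect. Each simulation starts 100 beads
uniformly at random on the grid nodes of the top half of the box
(y ≥ 1 µm, inclusive) and runs for up to 60 s of simulated time; walkers
are independent (no excluded volume, no bead–bead interaction, no
hydrodynamics) and the walk is 2-D by construction.

Two details of the verbal model are ambiguous on a lattice, and both are
exposed as explicit configuration rather than silently fixed:

* **Step rule.** The stated rule — stay or move to one of 4 neighbours,
  each with probability 1/5 (`lazy5`) — has per-step variance
  $\tfrac{2}{5}\Delta x^2$ per axis and therefore an effective
  diffusivity $D = \Delta x^2 / (5\Delta t) = 8$ µm²/s, *not* the
  10 µm²/s implied by the relation $D \approx \Delta x^2/(4\Delta t)$ used
  to derive Δt = 10⁻⁵ s from D = 10⁻⁷ cm²/s. The package implements
  `lazy5` as the default out of fidelity to the stated algorithm and
  provides `move4` (no stay option, probability 1/4 each) as the variant
  that realises D = 10 µm²/s. `msd_diagnostic()` verifies either variance
  law empirically on a free walk.
* **Reflection rule.** `reject_stay` (default) cancels an off-domain move,
  leaving the bead in place for that step; it preserves detailed balance
  with a uniform stationary distribution, so the distribution of binding
  locations along x stays uniform. `mirror` bounces the bead back one
  node instead, which perturbs edge statistics. Depressed binding
  frequency at the fiber ends (x = 0 and 2 µm) is an observation the
  symmetric stated rule cannot produce, so the package *reports* edge
  behaviour per reflection variant rather than asserting a dip.

Binding is recorded the instant a move lands on the bottom row (corners
included); the bind time is the post-move time, always an exact multiple
of Δt. A simulation terminates early once every bead is bound; beads still
unbound at 60 s are recorded as censored and excluded from mean-bind-time
summaries (at the default geometry fewer than 1 in 10⁵ trajectories are
censored, so the choice is immaterial in practice).

### The first-passage oracle

The y-marginal of the `lazy5` walk is itself a lazy 1-D walk (down/up with
probability 1/5 each), so the binding time is a first-passage time with
reflecting top and absorbing bottom. In the continuum limit the mean from
a uniform start on $y \in [1, 2]$ is

$$ \bar T = \frac{1}{2 D_y} \int_1^2 y\,(4 - y)\,\mathrm{d}y
   = \frac{11}{48}\ \mathrm{s} \approx 0.229\ \mathrm{s}, \quad D_y = 8\ \mu m^2/s. $$

The test suite uses the sharper *exact discrete* value (0.2308 s),
obtained by solving the tridiagonal mean and second-moment systems of the
101-node chain, and requires the ensemble mean to agree within three
standard errors. Ensembles are seeded by drawing one sub-seed per
simulation from the master seed, so results are bit-for-bit reproducible
and any single simulation can be re-run in isolation.

The test and acceptance ensembles use 50 simulations × 100 beads (5,000
trajectories), which puts the standard error of the mean binding time near
0.003 s; the full 500-simulation ensemble is available through the same
interface.

## Fate records and their statistics

The unit of observation is one fiber. Records are validated strictly:
cleaved fibers need a cleavage frame ≥ 2 (frame 1 is captured at plasmin
addition), a site (`ridge`/`length`) and — for ridge cleavage — a
further-digestion outcome; bundling/elongation flags belong to uncleaved
fibers only. Cleavage times are `frame × 30 s − 30 s`.

Percentages are never detached from their denominators: elongation and
bundling rates are out of *uncleaved* fibers, bundled→elongated out of
*bundled* fibers, site rates out of *cleaved* fibers, and further-digestion
out of *ridge-cleaved* fibers. Empty denominators yield absent (NA)
percentages, not zeros. Pooled fractions (summed counts) and across-trial
means ± SE of per-trial percentages are both computed and clearly
labelled, because the two aggregations differ whenever trials contribute
unequal fiber counts — conflating them is the main hazard in reproducing
this kind of tabulation. The disjoint categories bundled-and-elongated,
bundled-only and elongated-only are all reported so that either "elongated"
convention can be derived.

Box–whisker summaries fix the quartile convention to linear interpolation
(`stats::quantile` type 7, the common spreadsheet default), since none is
stated for the source figures; whisker ends are the most extreme actual
data values within 1.5·IQR of the quartiles. Two-group comparisons use
classical one-way ANOVA (identical to the two-sided pooled t-test for two
groups; the identity F = t² is asserted in the tests), with zero-variance
input reported as p = 1 under a `degenerate` flag. Dose–response
regressions are OLS of per-trial percentages on log10 concentration by
default — the tested dilutions span two decades, making the log scale the
natural axis — with a linear-scale option.

## The synthetic generator

No raw per-fiber data are published, so the generator is a *calibration
stand-in*, not a mechanistic model of bead sheathing: each conditional
probability is a free parameter with a default chosen once to mirror the
observed trends, and parameter recovery — not reproduction of experimental
percentages — is what the pipeline tests assert.

Per fiber, with bead concentration $b$ (beads/µL) and plasmin
concentration $p$ (U/mL):

* P(uncleaved) $= \mathrm{logit}^{-1}\!\big(4.5\,(\log_{10} b - 9.7)
  - 0.6 \log_2 p\big)$ — a strong bead effect (≈ 99 % uncleaved at
  4.55 × 10¹⁰ beads/µL, ≈ 9 % at 1.52 × 10⁹) and a deliberately weak
  plasmin shift (≈ 53 %/45 %/31 % uncleaved at 0.7/1.0/2.0 U/mL for the
  middle bead dose).
* Given cleavage: ridge site with probability
  $\mathrm{logit}^{-1}\!\big(-2.4\,(\log_{10} b - 10.66)\big)$ (≈ 99 %
  at the lowest dose, 50 % at the highest); the cleavage frame is
  $2 + G$ with $G$ geometric on the 30 s frame grid — a memoryless
  per-frame cleavage hazard, the simplest model consistent with
  frame-censored observation — whose mean time
  $30\,e^{-12.1 + 1.333 \log_{10} b}$ s rises from ≈ 30 s to ≈ 247 s
  across the series; ridge-cleaved fibers show no further digestion with
  probability 0.525.
* Given no cleavage: bundling with probability 0.27; elongation with
  probability 0.714 if bundled and 0.185 otherwise.

Defaults for sample structure are 5 trials of 20 fibers per condition over
the six-dilution × three-plasmin grid; observed per-condition totals in
this kind of experiment range from ~30 to ~100 fibers, so 20 per trial is
a round representative choice.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: between-trial overdispersion (trials share one
probability), any coupling between cleavage time and site, drift within
an acquisition, or the spatial correlations that make neighbouring fibers
bundle together. Recovery tests (`recover_parameters()`) check that
empirical conditional frequencies fall within three binomial standard
errors of their configured values at ≈ 200 fibers per condition and that
the regression stage recovers the sign of the configured dose–response;
a zero-slope variant of the generator calibrates the regression's type-I
error (slope p-values uniform on (0, 1)).

## Numerical and degenerate-input choices

* Concentrations, volumes and doses are computed in double precision and
  rounded only for display.
* `dilute()` rejects factors below 1; schedules that gate more exposure
  time than the acquisition contains are rejected.
* Simulations with `max_time = 0` simply return all beads unbound;
  `run_ensemble()` with one simulation equals that simulation's own
  aggregation.
* Regression requires ≥ 3 points and ≥ 2 distinct x values; single-
  condition input raises an explicit error rather than returning NA.
* The KS and chi-square calibration tests run at sizes (150 replicates,
  ~10⁴ fibers) chosen to keep the whole suite comfortably within a couple
  of minutes on one core while leaving the three-standard-error bands
  meaningful.

## Known limitations

The simulator is 2-D and irreversible by design — binding kinetics
(on/off rates) of the bead–fibrin interaction are unknown, so absorption
is the only defensible boundary condition, and no attempt is made to model
unbinding or saturation. The fate taxonomy takes manual image annotation
as ground truth; nothing here segments images. Experimental per-trial
percentages whose raw data are not published (trial means ± SE, raw
cleavage-time distributions, specific t-test p-values) are out of scope as
reproduction targets.
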