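# beadlysis

Quantitative machinery for studying how fluorescent nanobead labeling
alters in vitro fibrinolysis of single fibrin fibers.

Fibrin fibers — the structural scaffold of blood clots — are often labeled
with 20 nm carboxylate-modified polystyrene fluorospheres so that their
digestion by plasmin can be followed under a fluorescence microscope. The
labeling itself is not inert: at high bead concentrations fibers stop
cleaving, uncleaved fibers lose tension ("elongate"), cleaved fragments
"bundle" with neighbours, the cleavage site shifts away from the ridge
supports, and cleavage slows down. `beadlysis` packages the arithmetic,
simulation and statistics needed to quantify these effects:

- **Dosimetry** — bead number concentration from a solids fraction
  (N/mL = 6·C·10¹² / (ρ·π·d³)), dilution series, the beads-per-fiber-volume
  dose unit (expected beads inside one 20 µm × 100 nm fiber cylinder,
  ≈ 0.157 µm³), and the illumination energy dose of continuous vs
  shutter-gated time-lapse imaging.
- **Diffusion–binding Monte Carlo** — a 2-D lattice random walk of beads in
  a 2 µm × 2 µm box (Δx = 0.02 µm, Δt = 10⁻⁵ s) with reflecting top/left/
  right walls and an absorbing bottom row representing the fiber; at each
  step a bead stays or moves to one of its 4 neighbours with probability
  1/5 each. Ensembles summarise binding frequency and mean binding time as
  a function of location along the fiber, with an Rcpp kernel for speed and
  deterministic per-simulation seeding.
- **Outcome statistics** — validation and tabulation of per-fiber fate
  records (cleaved?, cleavage frame/site, further digestion, bundled?,
  elongated?), frame-to-time conversion (time = 30 s × frame − 30 s),
  box-whisker summaries with interpolated quartiles and 1.5·IQR whiskers,
  two-group one-way ANOVA, and OLS regression of outcome percentages
  against log10 concentration.
- **Synthetic fate records** — a seeded hierarchical generator (logistic
  cleavage probability in log10 bead concentration with a weak plasmin
  shift, concentration-dependent cleavage site and geometric frame-hazard
  cleavage times, conditional bundling→elongation coupling) so that the
  whole tabulate/test/regress pipeline is testable end to end without
  microscopy data.

## Worked example

```r
library(beadlysis)

# labeling dose across the standard dilution series
dilution_series()[, c("factor", "beads_per_ul_3sf", "beads_per_fiber_2sf")]
#>   factor beads_per_ul_3sf beads_per_fiber_2sf
#> 1    100         4.55e+10               7.100
#> 2    300         1.52e+10               2.400
#> 3   1000         4.55e+09               0.710
#> 4   2000         2.27e+09               0.360
#> 5   3000         1.52e+09               0.240
#> 6  10000         4.55e+08               0.071

# bead diffusion to the fiber: 50 independent simulations of 100 beads
run_ensemble(sim_config(master_seed = 7L), n_sims = 50)
#> Binding summary over 50 simulations x 100 beads:
#>   bound: 100.00% of trajectories (0 censored)
#>   mean bind time: 0.2296 s
#>   binding fraction by x: 0.66% to 1.32% across 101 nodes

# synthetic fate records -> tabulation -> dose-response regression
rec <- generate_fate_records(generator_params(master_seed = 7L))
tab <- tabulate_outcomes(rec)
pt  <- tab$per_trial[tab$per_trial$plasmin_concentration == 1, ]
regress_vs_concentration(pt$bead_concentration, pt$pct_uncleaved)$slope
#> [1] 56.3   # percentage points of uncleaved fibers per decade of beads
```

The stock concentration works out to 4.55 × 10¹² beads/µL (≈ 714 beads per
fiber volume), the mean binding time agrees with the analytic 1-D
first-passage value of ≈ 0.23 s for the lazy walk (effective
D_y = 8 µm²/s), and a one-hour acquisition deposits 0.612 J of light with
the shutter open versus 0.0041 J gated — a 150-fold difference.

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "beadlysis", package = "beadlysis")` with subcommands
`dosimetry`, `simulate`, `synth`, `tabulate`, `cleavage-times`, `regress`,
`recover` and `pipeline`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","beadlysis",package="beadlysis"))')" \
    synth --seed 7 --out records.csv
```

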