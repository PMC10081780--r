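#' Describe a bead stock preparation
#'
#' Carboxylate-modified polystyrene fluorospheres are supplied as a
#' weight-volume fraction of solids. Together with the material density and
#' bead diameter this determines the number concentration of the stock.
#'
#' @param solids_fraction Weight-volume fraction of bead solids,
#'   dimensionless (0.02 for a "2% solids" stock). Must lie in (0, 1].
#' @param material_density Density of the bead material in g/mL
#'   (1.05 for polystyrene).
#' @param bead_diameter Bead diameter in micrometres (0.02 for 20 nm beads).
#' @param dilution_factor Dilution from stock, >= 1 (1 = undiluted).
#'
#' @return An object of class `bead_prep`.
#' @seealso [beads_per_ml()], [dilution_series()]
#' @export
#' @examples
#' prep <- bead_prep()            # 2% solids, 20 nm polystyrene stock
#' beads_per_ml(prep)
bead_prep <- function(solids_fraction = 0.02, material_density = 1.05,
                      bead_diameter = 0.02, dilution_factor = 1) {
  stopifnot(is.numeric(solids_fraction), length(solids_fraction) == 1L,
            is.numeric(material_density), length(material_density) == 1L,
            is.numeric(bead_diameter), length(bead_diameter) == 1L,
            is.numeric(dilution_factor), length(dilution_factor) == 1L)
  if (!(solids_fraction >= 0 && solids_fraction <= 1))
    stop("'solids_fraction' must lie in [0, 1]", call. = FALSE)
  if (material_density <= 0)
    stop("'material_density' must be positive", call. = FALSE)
  if (bead_diameter <= 0)
    stop("'bead_diameter' must be positive", call. = FALSE)
  if (dilution_factor < 1)
    stop("'dilution_factor' must be >= 1", call. = FALSE)
  structure(list(solids_fraction = solids_fraction,
                 material_density = material_density,
                 bead_diameter = bead_diameter,
                 dilution_factor = dilution_factor),
            class = "bead_prep")
}

#' @export
print.bead_prep <- function(x, ...) {
  cat("Bead preparation:\n")
  cat(sprintf("  solids fraction : %g (w/v)\n", x$solids_fraction))
  cat(sprintf("  material density: %g g/mL\n", x$material_density))
  cat(sprintf("  bead diameter   : %g um (%g nm)\n",
              x$bead_diameter, 1e3 * x$bead_diameter))
  cat(sprintf("  dilution factor : %g\n", x$dilution_factor))
  cat(sprintf("  concentration   : %.3g beads/uL\n",
              beads_per_ul(beads_per_ml(x))))
  invisible(x)
}

#' Bead number concentration of a preparation
#'
#' Manufacturer's formula for the number of beads per millilitre:
#' \deqn{N/mL = \frac{6 C \times 10^{12}}{\rho \pi d^3}}
#' where `C` is the solids weight-volume fraction, `rho` the material density
#' in g/mL and `d` the bead diameter in micrometres. The preparation's
#' `dilution_factor` is applied afterwards.
#'
#' @param prep A [bead_prep()] object.
#' @return Bead concentration in beads/mL (divide by 1e3 for beads/uL, see
#'   [beads_per_ul()]).
#' @export
#' @examples
#' beads_per_ml(bead_prep(0.02, 1.05, 0.02))   # ~4.55e15 beads/mL
beads_per_ml <- function(prep) {
  stopifnot(inherits(prep, "bead_prep"))
  undiluted <- 6 * prep$solids_fraction * 1e12 /
    (prep$material_density * pi * prep$bead_diameter^3)
  dilute(undiluted, prep$dilution_factor)
}

#' Convert beads/mL to beads/uL (and back)
#'
#' @param conc_per_ml Concentration in beads/mL.
#' @return Concentration in beads/uL.
#' @export
beads_per_ul <- function(conc_per_ml) {
  stopifnot(is.numeric(conc_per_ml), all(conc_per_ml >= 0))
  conc_per_ml / 1e3
}

#' @rdname beads_per_ul
#' @param conc_per_ul Concentration in beads/uL.
#' @export
beads_per_ml_from_ul <- function(conc_per_ul) {
  stopifnot(is.numeric(conc_per_ul), all(conc_per_ul >= 0))
  conc_per_ul * 1e3
}

#' Dilute a concentration
#'
#' @param stock Stock concentration (any concentration unit).
#' @param factor Dilution factor(s), >= 1; a 1:1000 dilution has factor 1000.
#' @return `stock / factor`, in the unit of `stock`.
#' @export
#' @examples
#' dilute(4.55e12, 1000)   # 1:1000 dilution
dilute <- function(stock, factor) {
  stopifnot(is.numeric(stock), is.numeric(factor))
  if (any(stock < 0)) stop("'stock' must be non-negative", call. = FALSE)
  if (any(factor < 1)) stop("dilution 'factor' must be >= 1", call. = FALSE)
  stock / factor
}

#' Cylindrical reference geometry of a fibrin fiber
#'
#' The beads-per-fiber-volume normalisation uses a reference cylinder of
#' 20 um length and 100 nm diameter (volume ~0.157 um^3).
#'
#' @param length Fiber length in micrometres.
#' @param diameter Fiber diameter in micrometres.
#' @return An object of class `fiber_geometry`.
#' @export
fiber_geometry <- function(length = 20, diameter = 0.1) {
  stopifnot(is.numeric(length), length(length) == 1L,
            is.numeric(diameter), length(diameter) == 1L)
  if (length <= 0) stop("fiber 'length' must be positive", call. = FALSE)
  if (diameter <= 0) stop("fiber 'diameter' must be positive", call. = FALSE)
  structure(list(length = length, diameter = diameter),
            class = "fiber_geometry")
}

#' @export
print.fiber_geometry <- function(x, ...) {
  cat(sprintf("Fiber geometry: L = %g um, d = %g um, volume = %.4g um^3\n",
              x$length, x$diameter, fiber_volume(x)))
  invisible(x)
}

#' Volume of the reference fiber cylinder
#'
#' @param geom A [fiber_geometry()] object.
#' @return Volume in cubic micrometres, at full precision (0.15708 um^3 for
#'   the defaults; round only when reporting).
#' @export
fiber_volume <- function(geom) {
  stopifnot(inherits(geom, "fiber_geometry"))
  pi * (geom$diameter / 2)^2 * geom$length
}

#' Expected number of beads within one fiber volume
#'
#' Expresses a bead solution concentration as the expected count of beads
#' inside one reference fiber cylinder, the natural dose unit for labeling.
#'
#' @param conc_per_ul Bead concentration in beads/uL.
#' @param geom A [fiber_geometry()] object.
#' @return Dimensionless expected bead count (1 uL = 1e9 um^3).
#' @export
#' @examples
#' beads_per_fiber_volume(4.55e12)   # ~714 at stock concentration
beads_per_fiber_volume <- function(conc_per_ul, geom = fiber_geometry()) {
  stopifnot(is.numeric(conc_per_ul))
  if (any(conc_per_ul < 0))
    stop("'conc_per_ul' must be non-negative", call. = FALSE)
  (conc_per_ul / 1e9) * fiber_volume(geom)
}

#' The dilution series of a bead stock
#'
#' @param prep A [bead_prep()] object (the undiluted stock).
#' @param factors Dilution factors; defaults to the series used in the
#'   labeling experiments (1:100 through 1:10,000).
#' @param geom Reference [fiber_geometry()] for the beads-per-fiber column.
#' @return A data.frame with columns `factor`, `beads_per_ul`,
#'   `beads_per_fiber_volume`, plus display-rounded columns
#'   `beads_per_ul_3sf` (3 significant figures) and `beads_per_fiber_2sf`.
#' @export
dilution_series <- function(prep = bead_prep(),
                            factors = c(100, 300, 1000, 2000, 3000, 10000),
                            geom = fiber_geometry()) {
  stock_ul <- beads_per_ul(beads_per_ml(prep))
  conc <- dilute(stock_ul, factors)
  data.frame(
    factor = factors,
    beads_per_ul = conc,
    beads_per_fiber_volume = beads_per_fiber_volume(conc, geom),
    beads_per_ul_3sf = signif(conc, 3),
    beads_per_fiber_2sf = signif(beads_per_fiber_volume(conc, geom), 2)
  )
}

#' Illumination schedule of a time-lapse experiment
#'
#' Either the shutter stays open for the whole acquisition (`continuous`) or
#' it opens only during each exposure (`gated`). Default power is 170 uW,
#' the midpoint of the 160-180 uW measured range; the default gated schedule
#' is one 200 ms exposure every 30 s over one hour (120 exposures).
#'
#' @param power Illumination power in watts.
#' @param mode `"continuous"` or `"gated"`.
#' @param total_duration Total acquisition time in seconds.
#' @param n_exposures Number of gated exposures.
#' @param exposure_time Single exposure duration in seconds.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(power = 170e-6,
                           mode = c("continuous", "gated"),
                           total_duration = 3600,
                           n_exposures = 120, exposure_time = 0.2) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(power), length(power) == 1L,
            is.numeric(total_duration), length(total_duration) == 1L)
  if (power < 0) stop("'power' must be non-negative", call. = FALSE)
  if (total_duration < 0)
    stop("'total_duration' must be non-negative", call. = FALSE)
  if (mode == "gated") {
    stopifnot(is.numeric(n_exposures), n_exposures >= 0,
              is.numeric(exposure_time), exposure_time >= 0)
    if (n_exposures * exposure_time > total_duration)
      stop("gated schedule inconsistent: n_exposures * exposure_time ",
           "exceeds total_duration", call. = FALSE)
  }
  structure(list(power = power, mode = mode,
                 total_duration = total_duration,
                 n_exposures = n_exposures, exposure_time = exposure_time),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule (%s): %g uW over %g s", x$mode,
              1e6 * x$power, x$total_duration))
  if (x$mode == "gated")
    cat(sprintf(" (%d x %g s exposures)", x$n_exposures, x$exposure_time))
  cat(sprintf("; dose = %.4g J\n", light_dose(x)))
  invisible(x)
}

#' Energy deposited by an illumination schedule
#'
#' Continuous: `power * total_duration`. Gated: `power * n_exposures *
#' exposure_time`. At 170 uW, one hour of continuous light deposits 0.612 J,
#' while 120 exposures of 200 ms deposit 0.00408 J -- 150-fold less.
#'
#' @param schedule A [light_schedule()] object.
#' @return Energy in joules.
#' @export
light_dose <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (schedule$mode == "continuous")
    schedule$power * schedule$total_duration
  else
    schedule$power * schedule$n_exposures * schedule$exposure_time
}

#' Flat dosimetry report for one labeling condition
#'
#' Collects every derived dosimetry quantity into a flat named list suitable
#' for JSON serialisation. Concentrations are reported at full precision,
#' with 3-significant-figure display companions (2 for beads per fiber).
#'
#' @param prep A [bead_prep()] object.
#' @param geom A [fiber_geometry()] object.
#' @param continuous,gated [light_schedule()] objects for the two
#'   illumination modes.
#' @return A named list of scalars.
#' @export
dosimetry_report <- function(prep = bead_prep(), geom = fiber_geometry(),
                             continuous = light_schedule(mode = "continuous"),
                             gated = light_schedule(mode = "gated")) {
  per_ml <- beads_per_ml(prep)
  per_ul <- beads_per_ul(per_ml)
  dose_c <- light_dose(continuous)
  dose_g <- light_dose(gated)
  list(
    solids_fraction = prep$solids_fraction,
    material_density_g_per_ml = prep$material_density,
    bead_diameter_um = prep$bead_diameter,
    dilution_factor = prep$dilution_factor,
    beads_per_ml = per_ml,
    beads_per_ul = per_ul,
    beads_per_ul_3sf = signif(per_ul, 3),
    fiber_length_um = geom$length,
    fiber_diameter_um = geom$diameter,
    fiber_volume_um3 = fiber_volume(geom),
    beads_per_fiber_volume = beads_per_fiber_volume(per_ul, geom),
    beads_per_fiber_volume_2sf = signif(beads_per_fiber_volume(per_ul, geom), 2),
    light_dose_continuous_j = dose_c,
    light_dose_gated_j = dose_g,
    light_dose_ratio = if (dose_g > 0) dose_c / dose_g else NA_real_
  )
}
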