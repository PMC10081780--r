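#' Configuration of the lattice diffusion-binding simulation
#'
#' Beads diffuse on a square lattice inside a box with reflecting top, left
#' and right walls; the bottom row represents a fibrin fiber and absorbs
#' (irreversibly binds) any bead that reaches it. Defaults follow the
#' simulated labeling geometry: a 2 um x 2 um box, 0.02 um space step,
#' 1e-5 s time step, 100 beads started uniformly at random on grid nodes in
#' the top half of the box, run for 60 s of simulated time.
#'
#' Two step rules are available. `lazy5` is the stated algorithm: at each
#' time step a bead stays put or moves to one of its 4 nearest neighbours,
#' each with probability 1/5; its effective diffusivity is
#' `D = dx^2 / (5 dt)` = 8 um^2/s at the defaults. `move4` removes the stay
#' option (each neighbour with probability 1/4) and realises
#' `D = dx^2 / (4 dt)` = 10 um^2/s, the value the default time step was
#' derived from (see [timestep_from_D()]).
#'
#' "Reflecting" is ambiguous on a lattice, so the wall behaviour is
#' explicit: `reject_stay` (default) cancels an off-domain move, leaving the
#' bead in place for that step; `mirror` bounces it back one node. The
#' default preserves a uniform stationary distribution along x.
#'
#' @param domain_width,domain_height Box dimensions in um; must be exact
#'   multiples of `space_step`.
#' @param space_step Lattice spacing dx in um.
#' @param time_step Time step dt in seconds. If `NULL`, derived from
#'   `diffusion_coefficient` via [timestep_from_D()].
#' @param diffusion_coefficient Free diffusion coefficient in um^2/s used
#'   only when `time_step` is `NULL` (default 10, i.e. 1e-7 cm^2/s for a
#'   ~24 nm bead).
#' @param n_beads Number of independent beads per simulation.
#' @param max_time Simulated duration in seconds; beads unbound at
#'   `max_time` are recorded as censored.
#' @param step_rule `"lazy5"` or `"move4"`.
#' @param reflection_rule `"reject_stay"` or `"mirror"`.
#' @param master_seed Integer seed from which per-simulation seeds are
#'   spawned in [run_ensemble()].
#' @return An object of class `sim_config`.
#' @seealso [run_simulation()], [run_ensemble()], [msd_diagnostic()]
#' @export
sim_config <- function(domain_width = 2, domain_height = 2,
                       space_step = 0.02, time_step = 1e-5,
                       diffusion_coefficient = 10,
                       n_beads = 100, max_time = 60,
                       step_rule = c("lazy5", "move4"),
                       reflection_rule = c("reject_stay", "mirror"),
                       master_seed = 1L) {
  step_rule <- match.arg(step_rule)
  reflection_rule <- match.arg(reflection_rule)
  if (is.null(time_step))
    time_step <- timestep_from_D(space_step, diffusion_coefficient)
  stopifnot(space_step > 0, time_step > 0, n_beads >= 1,
            max_time >= 0, domain_width > 0, domain_height > 0)
  nx <- domain_width / space_step
  ny <- domain_height / space_step
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("domain dimensions must be exact multiples of 'space_step'",
         call. = FALSE)
  structure(list(domain_width = domain_width, domain_height = domain_height,
                 space_step = space_step, time_step = time_step,
                 diffusion_coefficient = diffusion_coefficient,
                 n_beads = as.integer(n_beads), max_time = max_time,
                 step_rule = step_rule, reflection_rule = reflection_rule,
                 master_seed = as.integer(master_seed),
                 nx = as.integer(round(nx)), ny = as.integer(round(ny))),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Lattice diffusion-binding configuration:\n")
  cat(sprintf("  domain    : %g x %g um, dx = %g um (%d x %d nodes)\n",
              x$domain_width, x$domain_height, x$space_step,
              x$nx + 1L, x$ny + 1L))
  cat(sprintf("  time      : dt = %g s, max %g s (%d steps)\n",
              x$time_step, x$max_time, max_steps(x)))
  cat(sprintf("  beads     : %d, step rule %s, walls %s\n",
              x$n_beads, x$step_rule, x$reflection_rule))
  cat(sprintf("  master_seed: %d\n", x$master_seed))
  invisible(x)
}

max_steps <- function(config) as.integer(floor(config$max_time / config$time_step))

#' Lattice time step implied by a diffusion coefficient
#'
#' Inverts the relation `D ~ dx^2 / (4 dt)` used to pick the simulation time
#' step: for dx = 0.02 um and D = 10 um^2/s (1e-7 cm^2/s), dt = 1e-5 s.
#'
#' @param dx Lattice spacing in um.
#' @param D Diffusion coefficient in um^2/s.
#' @return Time step in seconds, `dx^2 / (4 D)`.
#' @export
timestep_from_D <- function(dx, D) {
  stopifnot(is.numeric(dx), is.numeric(D))
  if (any(dx <= 0)) stop("'dx' must be positive", call. = FALSE)
  if (any(D <= 0)) stop("'D' must be positive", call. = FALSE)
  dx^2 / (4 * D)
}

step_rule_code <- function(rule) match(rule, c("lazy5", "move4")) - 1L
refl_rule_code <- function(rule) match(rule, c("reject_stay", "mirror")) - 1L

#' Run one diffusion-binding simulation
#'
#' Beads are initialised uniformly at random on grid nodes in the top half
#' of the box (y >= H/2, inclusive) and advanced in time steps until every
#' bead has bound or `max_time` is reached. Bound beads stop updating.
#' Binding occurs the instant a move lands on the bottom row; the bind time
#' is the post-move time and is always an exact multiple of the time step.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed for this simulation (defaults to the config's
#'   `master_seed`).
#' @param trace_every If positive, record all bead positions every
#'   `trace_every` time steps (for [export_trace()]); 0 disables recording.
#' @return An object of class `binding_sim`: a list with `states` (one row
#'   per bead: `bead`, `bound`, `bind_time`, `bind_x`, `final_x`,
#'   `final_y`), the `config`, the `seed`, and (if recorded) a `trace`.
#' @export
run_simulation <- function(config = sim_config(), seed = config$master_seed,
                           trace_every = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  # top half = nodes with y >= H/2 (inclusive); shared nodes allowed
  j_min <- as.integer(ceiling(config$ny / 2))
  i0 <- sample.int(config$nx + 1L, config$n_beads, replace = TRUE) - 1L
  j0 <- sample.int(config$ny - j_min + 1L, config$n_beads, replace = TRUE) +
    j_min - 1L
  res <- walk_absorb_cpp(i0, j0, config$nx, config$ny, max_steps(config),
                         step_rule_code(config$step_rule),
                         refl_rule_code(config$reflection_rule),
                         as.integer(trace_every))
  states <- data.frame(
    bead = seq_len(config$n_beads),
    bound = res$bound,
    bind_time = res$bind_step * config$time_step,
    bind_x = res$bind_node * config$space_step,
    final_x = res$final_i * config$space_step,
    final_y = res$final_j * config$space_step
  )
  out <- list(states = states, config = config, seed = seed)
  if (trace_every > 0) {
    out$trace <- list(frame_step = res$frame_step,
                      x = res$trace_i * config$space_step,
                      y = res$trace_j * config$space_step,
                      trace_every = as.integer(trace_every))
  }
  structure(out, class = "binding_sim")
}

#' @export
print.binding_sim <- function(x, ...) {
  n <- nrow(x$states)
  nb <- sum(x$states$bound)
  cat(sprintf("Diffusion-binding simulation (seed %d): %d/%d beads bound",
              x$seed, nb, n))
  if (nb > 0)
    cat(sprintf("; mean bind time %.3g s", mean(x$states$bind_time,
                                                na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Run an ensemble of simulations and summarise binding by location
#'
#' Runs `n_sims` independent simulations, each seeded deterministically from
#' the config's `master_seed` (per-simulation seeds are drawn once with
#' `sample.int` under the master seed, so the ensemble is reproducible
#' bit-for-bit and individual simulations can be re-run in isolation).
#'
#' @param config A [sim_config()] object.
#' @param n_sims Number of independent simulations (500 at the scale used
#'   for the binding-location figures).
#' @return An object of class `binding_summary`: `by_location` has one row
#'   per lattice x-node with `x_um`, `n_bound`, `bind_fraction_pct` (percent
#'   of all bead trajectories in the ensemble that bound at that node; these
#'   sum to the overall bound percentage) and `mean_bind_time_s` (mean over
#'   beads that bound there; censored beads never bind and are excluded).
#'   Also carries `overall_bound_fraction`, `mean_bind_time_s` (grand mean
#'   over all bound beads), `n_censored`, `n_simulations`, `n_beads`,
#'   and the `config`.
#' @export
run_ensemble <- function(config = sim_config(), n_sims = 500L) {
  stopifnot(inherits(config, "sim_config"), n_sims >= 1)
  set.seed(config$master_seed)
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  nx <- config$nx
  n_bound_node <- integer(nx + 1L)
  time_sum_node <- numeric(nx + 1L)
  n_censored <- 0L
  for (k in seq_len(n_sims)) {
    s <- run_simulation(config, seed = sim_seeds[k])$states
    b <- s$bound
    n_censored <- n_censored + sum(!b)
    if (any(b)) {
      node <- as.integer(round(s$bind_x[b] / config$space_step)) + 1L
      n_bound_node <- n_bound_node + tabulate(node, nbins = nx + 1L)
      time_sum_node <- time_sum_node +
        vapply(seq_len(nx + 1L), function(i)
          sum(s$bind_time[b][node == i]), numeric(1))
    }
  }
  n_traj <- n_sims * config$n_beads
  by_location <- data.frame(
    x_um = (0:nx) * config$space_step,
    n_bound = n_bound_node,
    bind_fraction_pct = 100 * n_bound_node / n_traj,
    mean_bind_time_s = ifelse(n_bound_node > 0,
                              time_sum_node / n_bound_node, NA_real_)
  )
  structure(list(by_location = by_location,
                 overall_bound_fraction = sum(n_bound_node) / n_traj,
                 mean_bind_time_s = sum(time_sum_node) / sum(n_bound_node),
                 n_censored = n_censored,
                 n_simulations = as.integer(n_sims),
                 n_beads = config$n_beads,
                 config = config),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf("Binding summary over %d simulations x %d beads:\n",
              x$n_simulations, x$n_beads))
  cat(sprintf("  bound: %.2f%% of trajectories (%d censored)\n",
              100 * x$overall_bound_fraction, x$n_censored))
  cat(sprintf("  mean bind time: %.4g s\n", x$mean_bind_time_s))
  cat(sprintf("  binding fraction by x: %.3g%% to %.3g%% across %d nodes\n",
              min(x$by_location$bind_fraction_pct),
              max(x$by_location$bind_fraction_pct),
              nrow(x$by_location)))
  invisible(x)
}

#' @export
summary.binding_summary <- function(object, ...) {
  loc <- object$by_location
  cat(sprintf("Ensemble: %d sims x %d beads (master seed %d)\n",
              object$n_simulations, object$n_beads,
              object$config$master_seed))
  cat(sprintf("Overall bound fraction: %.4f; grand mean bind time: %.4g s\n",
              object$overall_bound_fraction, object$mean_bind_time_s))
  interior <- loc[loc$x_um > 0 & loc$x_um < object$config$domain_width, ]
  edges <- loc[loc$x_um == 0 | loc$x_um == object$config$domain_width, ]
  cat(sprintf("Binding fraction: interior mean %.3g%%, edge mean %.3g%%\n",
              mean(interior$bind_fraction_pct), mean(edges$bind_fraction_pct)))
  cat(sprintf("Mean bind time:   interior %.3g s, edges %.3g s\n",
              mean(interior$mean_bind_time_s, na.rm = TRUE),
              mean(edges$mean_bind_time_s, na.rm = TRUE)))
  invisible(object)
}

#' Plot binding frequency and mean binding time along the fiber
#'
#' @param x A `binding_summary` from [run_ensemble()].
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.binding_summary <- function(x, ...) {
  loc <- x$by_location
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(loc$x_um, loc$bind_fraction_pct, type = "h",
                 xlab = "location along fiber (um)",
                 ylab = "binding fraction (%)", ...)
  graphics::plot(loc$x_um, loc$mean_bind_time_s, type = "p", pch = 16,
                 cex = 0.5, xlab = "location along fiber (um)",
                 ylab = "mean bind time (s)", ...)
  invisible(x)
}

#' Mean-squared-displacement diagnostic of the walk
#'
#' Runs free-space walkers (no walls, no absorption) under the configured
#' step rule and reports the empirical per-axis displacement variance at
#' checkpoint step counts, together with the analytic expectation:
#' `(2/5) dx^2 n` per axis under `lazy5` and `(1/2) dx^2 n` under `move4`
#' (the latter recovering `D = dx^2 / (4 dt)`).
#'
#' @param config A [sim_config()] (its `space_step` and `step_rule` are
#'   used).
#' @param n_steps Number of steps to run.
#' @param n_walkers Number of independent walkers.
#' @param seed Integer seed.
#' @param n_checkpoints Number of evenly spaced checkpoints.
#' @return A data.frame with `step`, `var_x_um2`, `var_y_um2`,
#'   `expected_um2`.
#' @export
msd_diagnostic <- function(config = sim_config(), n_steps = 1e4,
                           n_walkers = 1e4, seed = config$master_seed,
                           n_checkpoints = 10L) {
  stopifnot(inherits(config, "sim_config"), n_steps >= 0, n_walkers >= 1)
  set.seed(seed)
  checkpoints <- unique(as.integer(round(
    seq(0, n_steps, length.out = n_checkpoints + 1L))))
  res <- walk_free_cpp(as.integer(n_walkers), checkpoints,
                       step_rule_code(config$step_rule))
  dx2 <- config$space_step^2
  per_step <- if (config$step_rule == "lazy5") 2 / 5 else 1 / 2
  var_row <- function(m) apply(m, 1, stats::var) * dx2
  data.frame(step = checkpoints,
             var_x_um2 = var_row(res$x),
             var_y_um2 = var_row(res$y),
             expected_um2 = per_step * dx2 * checkpoints)
}

#' Write a recorded simulation trace to CSV
#'
#' One row per bead per recorded frame, with frame index, simulation time
#' and lattice coordinates in um. Frames are `trace_every` time steps apart
#' (1e-3 s at the defaults with `trace_every = 100`).
#'
#' @param sim A `binding_sim` run with `trace_every > 0`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(sim, path) {
  stopifnot(inherits(sim, "binding_sim"))
  if (is.null(sim$trace))
    stop("simulation was run without trace recording; ",
         "use run_simulation(trace_every = ...)", call. = FALSE)
  tr <- sim$trace
  n_frames <- length(tr$frame_step)
  n_beads <- ncol(tr$x)
  df <- data.frame(
    frame = rep(seq_len(n_frames), each = n_beads),
    time_s = rep(tr$frame_step * sim$config$time_step, each = n_beads),
    bead = rep(seq_len(n_beads), times = n_frames),
    x_um = as.vector(t(tr$x)),
    y_um = as.vector(t(tr$y))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
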