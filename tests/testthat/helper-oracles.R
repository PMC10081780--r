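# Independent oracles used across the suite.

# Exact first-passage moments of the y-marginal walk: a lazy 1-D walk on
# nodes 0..ny that moves down or up with probability 1/5 each (stays
# otherwise), absorbing at 0, with the top move rejected at ny. Solves the
# tridiagonal systems for E[T] and E[T^2] from each start node and mixes
# them over a uniform start on j in {j_min..ny}. Entirely independent of
# the simulation kernel.
mfpt_oracle <- function(ny = 100, dt = 1e-5, j_min = 50) {
  A <- matrix(0, ny, ny)    # unknowns T_1..T_ny (T_0 = 0)
  for (j in 1:ny) {
    if (j < ny) A[j, j] <- 2 / 5 else A[j, j] <- 1 / 5
    if (j > 1) A[j, j - 1] <- -1 / 5
    if (j < ny) A[j, j + 1] <- -1 / 5
  }
  m1 <- solve(A, rep(dt, ny))
  # E[T^2]: (I-P) m2 = dt^2 + 2 dt (m1 - dt)  since P m1 = m1 - dt
  m2 <- solve(A, dt^2 + 2 * dt * (m1 - dt))
  start <- j_min:ny
  mean_t <- mean(m1[start])
  var_t <- mean(m2[start]) - mean_t^2
  list(mean = mean_t, sd = sqrt(var_t))
}

# Linear-interpolation quartiles written out from the definition
# (h = (n-1) p + 1 on the sorted sample), independent of stats::quantile.
quartile_interp <- function(v, p) {
  x <- sort(v)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Builders for fate records with prescribed outcome counts.
make_uncleaved <- function(n, bundled = FALSE, elongated = FALSE,
                           trial = "trial01", bead = 4.55e9, plasmin = 1.0) {
  if (n == 0) return(NULL)
  data.frame(trial_id = rep_len(trial, n),
             bead_concentration = rep_len(bead, n),
             plasmin_concentration = rep_len(plasmin, n), cleaved = FALSE,
             cleavage_frame = NA_integer_, cleavage_site = NA_character_,
             further_digestion = NA_character_,
             bundled = rep_len(bundled, n),
             elongated = rep_len(elongated, n))
}

make_cleaved <- function(n, site = "ridge", frame = 3L,
                         further = NULL,
                         trial = "trial01", bead = 4.55e9, plasmin = 1.0) {
  if (n == 0) return(NULL)
  site <- rep_len(site, n)
  if (is.null(further))
    further <- ifelse(site == "ridge", "recoil_collapse", NA_character_)
  data.frame(trial_id = rep_len(trial, n),
             bead_concentration = rep_len(bead, n),
             plasmin_concentration = rep_len(plasmin, n), cleaved = TRUE,
             cleavage_frame = as.integer(rep_len(frame, n)),
             cleavage_site = site,
             further_digestion = rep_len(further, n),
             bundled = NA, elongated = NA)
}

bind_records <- function(...) {
  do.call(rbind, Filter(Negate(is.null), list(...)))
}
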