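#' Convert a cleavage frame index to a cleavage time
#'
#' Time-lapse frames are 1-based with frame 1 captured at plasmin addition,
#' so the cleavage time is `frame * interval - interval`: the first frame
#' that can show cleavage (frame 2) maps to 30 s at the default interval.
#'
#' @param frame 1-based index of the first frame showing cleavage.
#' @param interval Frame interval in seconds (default 30).
#' @return Cleavage time in seconds after plasmin addition.
#' @export
cleavage_time <- function(frame, interval = 30) {
  stopifnot(is.numeric(frame), is.numeric(interval), interval > 0)
  if (any(frame < 1, na.rm = TRUE))
    stop("'frame' must be >= 1 (frame 1 is at plasmin addition)",
         call. = FALSE)
  frame * interval - interval
}

fate_columns <- c("trial_id", "bead_concentration", "plasmin_concentration",
                  "cleaved", "cleavage_frame", "cleavage_site",
                  "further_digestion", "bundled", "elongated")

#' Validate a table of per-fiber fate records
#'
#' A fate record describes one observed fiber: its condition (trial, bead
#' and plasmin concentration) and its lysis outcome. Cleaved fibers carry a
#' cleavage frame (>= 2), a cleavage site (`"ridge"` or `"length"`) and,
#' for ridge cleavage, a further-digestion outcome (`"recoil_collapse"` or
#' `"none"`). Uncleaved fibers carry the `bundled` and `elongated` flags;
#' cleaved fibers must not.
#'
#' @param records A data.frame with columns `trial_id`,
#'   `bead_concentration`, `plasmin_concentration`, `cleaved`,
#'   `cleavage_frame`, `cleavage_site`, `further_digestion`, `bundled`,
#'   `elongated`.
#' @return `records`, invisibly, if valid; otherwise an error listing the
#'   offending rows.
#' @export
validate_fate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(fate_columns, names(records))
  if (length(missing_cols))
    stop("missing fate-record columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- list(
    "bead_concentration must be >= 0" =
      bad(records$bead_concentration < 0),
    "plasmin_concentration must be >= 0" =
      bad(records$plasmin_concentration < 0),
    "cleaved must be TRUE/FALSE" = which(is.na(records$cleaved)),
    "cleaved fibers need cleavage_frame >= 2" =
      which(records$cleaved &
              (is.na(records$cleavage_frame) | records$cleavage_frame < 2)),
    "uncleaved fibers must not carry a cleavage_frame" =
      which(!records$cleaved & !is.na(records$cleavage_frame)),
    "cleaved fibers need cleavage_site ridge|length" =
      which(records$cleaved &
              !(records$cleavage_site %in% c("ridge", "length"))),
    "uncleaved fibers must not carry a cleavage_site" =
      which(!records$cleaved & !is.na(records$cleavage_site)),
    "ridge-cleaved fibers need further_digestion recoil_collapse|none" =
      which(records$cleaved &
              records$cleavage_site %in% "ridge" &
              !(records$further_digestion %in% c("recoil_collapse", "none"))),
    "only ridge-cleaved fibers carry further_digestion" =
      which(!(records$cleaved & records$cleavage_site %in% "ridge") &
              !is.na(records$further_digestion)),
    "uncleaved fibers need bundled TRUE/FALSE" =
      which(!records$cleaved & is.na(records$bundled)),
    "uncleaved fibers need elongated TRUE/FALSE" =
      which(!records$cleaved & is.na(records$elongated)),
    "cleaved fibers must not carry bundled/elongated flags" =
      which(records$cleaved &
              (records$bundled %in% TRUE | records$elongated %in% TRUE))
  )
  problems <- problems[vapply(problems, length, integer(1)) > 0]
  if (length(problems)) {
    msgs <- vapply(seq_along(problems), function(i)
      sprintf("%s (rows %s)", names(problems)[i],
              paste(utils::head(problems[[i]], 10), collapse = ", ")),
      character(1))
    stop("invalid fate records:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(records)
}

pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

#' Tabulate per-fiber lysis outcomes by condition
#'
#' Counts and percentages per condition (bead concentration x plasmin
#' concentration), with each percentage tied to its explicit denominator:
#' elongation and bundling rates are out of uncleaved fibers, the
#' bundled-then-elongated rate is out of bundled fibers, cleavage-site rates
#' are out of cleaved fibers, and the no-further-digestion rate is out of
#' ridge-cleaved fibers. Bundled-and-elongated, bundled-only and
#' elongated-only are disjoint categories, so any reporting convention can
#' be derived.
#'
#' Pooled percentages (from summed counts) and across-trial means +/- SE of
#' per-trial percentages are both computed and kept clearly apart: the two
#' aggregations generally differ when trials have unequal fiber counts.
#'
#' @param records A validated fate-record data.frame (see
#'   [validate_fate_records()]).
#' @return An object of class `outcome_table` with components `counts`
#'   (one row per condition), `percentages` (pooled, with denominators),
#'   and `per_trial` (per-trial percentages plus across-trial mean and SE).
#' @export
tabulate_outcomes <- function(records) {
  validate_fate_records(records)
  records$.cond <- interaction(records$bead_concentration,
                               records$plasmin_concentration, drop = TRUE)
  conds <- split(records, records$.cond)
  count_one <- function(r) {
    unc <- r[!r$cleaved, ]
    clv <- r[r$cleaved, ]
    ridge <- clv[clv$cleavage_site == "ridge", ]
    data.frame(
      bead_concentration = r$bead_concentration[1],
      plasmin_concentration = r$plasmin_concentration[1],
      n_total = nrow(r),
      n_trials = length(unique(r$trial_id)),
      n_cleaved = nrow(clv),
      n_uncleaved = nrow(unc),
      n_bundled = sum(unc$bundled),
      n_bundled_and_elongated = sum(unc$bundled & unc$elongated),
      n_bundled_only = sum(unc$bundled & !unc$elongated),
      n_elongated_without_bundling = sum(!unc$bundled & unc$elongated),
      n_tense = sum(!unc$bundled & !unc$elongated),
      n_ridge_cleaved = nrow(ridge),
      n_length_cleaved = sum(clv$cleavage_site == "length"),
      n_recoil_collapse = sum(ridge$further_digestion == "recoil_collapse"),
      n_no_further_digestion = sum(ridge$further_digestion == "none")
    )
  }
  counts <- do.call(rbind, lapply(conds, count_one))
  rownames(counts) <- NULL
  counts <- counts[order(counts$plasmin_concentration,
                         counts$bead_concentration), ]

  percentages <- data.frame(
    bead_concentration = counts$bead_concentration,
    plasmin_concentration = counts$plasmin_concentration,
    pct_uncleaved = pct(counts$n_uncleaved, counts$n_total),
    pct_bundled_of_uncleaved = pct(counts$n_bundled, counts$n_uncleaved),
    pct_elongated_of_bundled = pct(counts$n_bundled_and_elongated,
                                   counts$n_bundled),
    pct_elongated_without_bundling_of_uncleaved =
      pct(counts$n_elongated_without_bundling, counts$n_uncleaved),
    pct_ridge_of_cleaved = pct(counts$n_ridge_cleaved, counts$n_cleaved),
    pct_length_of_cleaved = pct(counts$n_length_cleaved, counts$n_cleaved),
    pct_no_further_of_ridge = pct(counts$n_no_further_digestion,
                                  counts$n_ridge_cleaved)
  )

  trial_split <- split(records,
                       list(records$.cond, records$trial_id), drop = TRUE)
  trial_counts <- do.call(rbind, lapply(trial_split, function(r) {
    cbind(trial_id = r$trial_id[1], count_one(r))
  }))
  rownames(trial_counts) <- NULL
  per_trial <- data.frame(
    trial_id = trial_counts$trial_id,
    bead_concentration = trial_counts$bead_concentration,
    plasmin_concentration = trial_counts$plasmin_concentration,
    n_total = trial_counts$n_total,
    pct_uncleaved = pct(trial_counts$n_uncleaved, trial_counts$n_total),
    pct_bundled_of_uncleaved = pct(trial_counts$n_bundled,
                                   trial_counts$n_uncleaved),
    pct_elongated_without_bundling_of_uncleaved =
      pct(trial_counts$n_elongated_without_bundling,
          trial_counts$n_uncleaved),
    pct_ridge_of_cleaved = pct(trial_counts$n_ridge_cleaved,
                               trial_counts$n_cleaved)
  )
  key <- c("bead_concentration", "plasmin_concentration")
  agg <- function(col) {
    m <- stats::aggregate(per_trial[[col]], per_trial[key],
                          function(v) {
                            v <- v[!is.na(v)]
                            c(mean = mean(v),
                              se = stats::sd(v) / sqrt(length(v)),
                              n = length(v))
                          })
    out <- cbind(m[key], as.data.frame(m$x))
    names(out)[3:5] <- paste0(col, c("_trial_mean", "_trial_se", "_n_trials"))
    out
  }
  trial_summary <- Reduce(function(a, b) merge(a, b, by = key),
                          lapply(c("pct_uncleaved", "pct_bundled_of_uncleaved",
                                   "pct_elongated_without_bundling_of_uncleaved",
                                   "pct_ridge_of_cleaved"), agg))
  trial_summary <- trial_summary[order(trial_summary$plasmin_concentration,
                                       trial_summary$bead_concentration), ]
  rownames(trial_summary) <- NULL

  structure(list(counts = counts, percentages = percentages,
                 per_trial = per_trial, trial_summary = trial_summary),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, digits = 3, ...) {
  cat(sprintf("Outcome table: %d condition(s), %d fibers\n",
              nrow(x$counts), sum(x$counts$n_total)))
  cat("\nCounts:\n")
  print(x$counts, digits = digits, row.names = FALSE)
  cat("\nPooled percentages (denominators as named):\n")
  print(x$percentages, digits = digits, row.names = FALSE)
  cat("\nAcross-trial means +/- SE of per-trial percentages:\n")
  print(x$trial_summary, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Box-and-whisker summary of a sample
#'
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`); whisker ends are the most extreme data
#' values within 1.5 interquartile ranges of the quartiles, and values
#' beyond the whiskers are listed as outliers.
#'
#' @param values Numeric sample (e.g. cleavage times in seconds), n >= 1.
#' @return An object of class `box_whisker`: `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, `outliers`, `mean`, `se`, `n`.
#' @export
box_whisker <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop("'values' must contain at least one non-missing value",
         call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  structure(list(
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    outliers = sort(values[values < lo_fence | values > hi_fence]),
    mean = mean(values),
    se = if (length(values) > 1)
      stats::sd(values) / sqrt(length(values)) else NA_real_,
    n = length(values)
  ), class = "box_whisker")
}

#' @export
print.box_whisker <- function(x, ...) {
  cat(sprintf("n = %d: median %.4g [Q1 %.4g, Q3 %.4g], whiskers [%.4g, %.4g]\n",
              x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high))
  cat(sprintf("mean +/- SE: %.4g +/- %.4g; %d outlier(s)%s\n",
              x$mean, x$se, length(x$outliers),
              if (length(x$outliers))
                paste0(": ", paste(x$outliers, collapse = ", ")) else ""))
  invisible(x)
}

#' Box-whisker summaries of cleavage times per condition
#'
#' @param records A validated fate-record data.frame.
#' @param interval Frame interval in seconds.
#' @return A named list of [box_whisker()] summaries, one per bead
#'   concentration (conditions with no cleaved fibers are omitted).
#' @export
cleavage_time_summaries <- function(records, interval = 30) {
  validate_fate_records(records)
  clv <- records[records$cleaved, ]
  if (nrow(clv) == 0) return(list())
  times <- cleavage_time(clv$cleavage_frame, interval)
  lapply(split(times, clv$bead_concentration), box_whisker)
}

#' One-way ANOVA between two groups
#'
#' Classical one-way fixed-effects ANOVA, which for two groups is
#' algebraically equivalent to the two-sided pooled-variance t-test
#' (F = t^2). Degenerate input with zero total variance is reported as
#' p = 1 with `degenerate = TRUE` rather than NaN.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A list with `F`, `df` (c(between, within)), `p_value`,
#'   `degenerate`.
#' @export
two_group_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (stats::var(y) == 0)
    return(list(F = 0, df = c(1, length(y) - 2), p_value = 1,
                degenerate = TRUE))
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab$`F value`[1], df = c(tab$Df[1], tab$Df[2]),
       p_value = tab$`Pr(>F)`[1], degenerate = FALSE)
}

#' Linear regression of an outcome percentage on concentration
#'
#' Ordinary least squares of per-trial percentages against bead (or
#' plasmin) concentration, with a two-sided t-test on the slope. The
#' default x-scale is log10(concentration) because the tested dilutions
#' span two decades; `x_scale = "linear"` regresses on the raw
#' concentration.
#'
#' @param concentration Concentration per observation (e.g. per trial).
#' @param percentage Outcome percentage per observation.
#' @param x_scale `"log10"` (default) or `"linear"`.
#' @return A list with `slope`, `intercept`, `p_value` (two-sided, slope),
#'   `slope_se`, `r_squared`, `n`, `x_scale`, and the underlying `fit`
#'   (an `lm` object).
#' @export
regress_vs_concentration <- function(concentration, percentage,
                                     x_scale = c("log10", "linear")) {
  x_scale <- match.arg(x_scale)
  keep <- !(is.na(concentration) | is.na(percentage))
  concentration <- concentration[keep]
  percentage <- percentage[keep]
  if (length(percentage) < 3)
    stop("need at least 3 observations", call. = FALSE)
  x <- if (x_scale == "log10") {
    if (any(concentration <= 0))
      stop("log10 x-scale requires positive concentrations", call. = FALSE)
    log10(concentration)
  } else concentration
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  fit <- stats::lm(percentage ~ x)
  cf <- summary(fit)$coefficients
  list(slope = cf["x", "Estimate"],
       intercept = cf["(Intercept)", "Estimate"],
       p_value = cf["x", "Pr(>|t|)"],
       slope_se = cf["x", "Std. Error"],
       r_squared = summary(fit)$r.squared,
       n = length(percentage), x_scale = x_scale, fit = fit)
}
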