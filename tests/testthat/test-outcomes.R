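test_that("cleavage time maps frames to seconds after plasmin addition", {
  expect_equal(cleavage_time(1), 0)
  expect_equal(cleavage_time(2), 30)
  expect_equal(cleavage_time(9), 240)
  expect_equal(cleavage_time(3, interval = 10), 20)
  expect_error(cleavage_time(0), "frame")
})

test_that("fate-record validation pinpoints offending rows", {
  good <- bind_records(make_uncleaved(2), make_cleaved(2))
  expect_silent(validate_fate_records(good))
  bad <- good
  bad$cleavage_frame[3] <- 1L          # cleaved at the plasmin-addition frame
  bad$bundled[4] <- TRUE               # cleaved fiber carrying a bundle flag
  expect_error(validate_fate_records(bad), "rows 3")
  expect_error(validate_fate_records(bad), "rows 4")
  expect_error(validate_fate_records(good[, -4]), "missing")
})

test_that("tabulation reproduces worked count-to-percentage examples", {
  # 363 uncleaved fibers: 98 bundled (of which 70 elongated),
  # 67 elongated without bundling
  unc <- bind_records(
    make_uncleaved(70, bundled = TRUE, elongated = TRUE),
    make_uncleaved(28, bundled = TRUE, elongated = FALSE),
    make_uncleaved(67, bundled = FALSE, elongated = TRUE),
    make_uncleaved(363 - 98 - 67, bundled = FALSE, elongated = FALSE))
  tab <- tabulate_outcomes(unc)
  expect_equal(tab$counts$n_uncleaved, 363)
  expect_equal(round(tab$percentages$pct_elongated_without_bundling_of_uncleaved,
                     1), 18.5)   # 67/363
  expect_equal(round(tab$percentages$pct_bundled_of_uncleaved, 1), 27.0)

  # 22 bundled fibers of which 20 elongated: 90.9%
  cond <- bind_records(
    make_uncleaved(20, bundled = TRUE, elongated = TRUE),
    make_uncleaved(2, bundled = TRUE, elongated = FALSE),
    make_uncleaved(22, bundled = FALSE, elongated = TRUE))
  expect_equal(round(tabulate_outcomes(cond)$percentages$pct_elongated_of_bundled,
                     1), 90.9)

  # cleavage sites: 179 of 455 cleaved at the ridge (39%)
  sites <- bind_records(
    make_cleaved(179, site = "ridge"),
    make_cleaved(455 - 179, site = "length"))
  ptab <- tabulate_outcomes(sites)$percentages
  expect_equal(round(ptab$pct_ridge_of_cleaved), 39)
  expect_equal(round(ptab$pct_length_of_cleaved), 61)

  # 7 of 8 bundled fibers elongated: 87.5%
  eight <- bind_records(
    make_uncleaved(7, bundled = TRUE, elongated = TRUE),
    make_uncleaved(1, bundled = TRUE, elongated = FALSE),
    make_uncleaved(4, bundled = FALSE, elongated = FALSE))
  expect_equal(tabulate_outcomes(eight)$percentages$pct_elongated_of_bundled,
               87.5)
})

test_that("every pooled percentage recomputes from its numerator/denominator", {
  records <- generate_fate_records(generator_params(master_seed = 21L))
  tab <- tabulate_outcomes(records)
  cnt <- tab$counts
  pp <- tab$percentages
  expect_equal(pp$pct_uncleaved, 100 * cnt$n_uncleaved / cnt$n_total)
  expect_equal(pp$pct_bundled_of_uncleaved,
               ifelse(cnt$n_uncleaved > 0,
                      100 * cnt$n_bundled / cnt$n_uncleaved, NA))
  expect_equal(pp$pct_ridge_of_cleaved,
               ifelse(cnt$n_cleaved > 0,
                      100 * cnt$n_ridge_cleaved / cnt$n_cleaved, NA))
  # disjoint uncleaved categories partition the uncleaved count
  expect_equal(cnt$n_bundled_and_elongated + cnt$n_bundled_only +
                 cnt$n_elongated_without_bundling + cnt$n_tense,
               cnt$n_uncleaved)
  expect_equal(cnt$n_ridge_cleaved + cnt$n_length_cleaved, cnt$n_cleaved)
  expect_true(all(cnt$n_recoil_collapse + cnt$n_no_further_digestion ==
                    cnt$n_ridge_cleaved))
})

test_that("tabulation is permutation-invariant and additive", {
  r <- generate_fate_records(generator_params(master_seed = 22L,
                                              n_trials = 2L))
  set.seed(1)
  shuffled <- r[sample(nrow(r)), ]
  t_all <- tabulate_outcomes(r)
  t_shuf <- tabulate_outcomes(shuffled)
  expect_equal(t_all$counts, t_shuf$counts)
  half <- nrow(r) %/% 2
  # counts over disjoint subsets sum to the counts over the union
  a <- tabulate_outcomes(r[seq_len(half), ])$counts
  b <- tabulate_outcomes(r[(half + 1):nrow(r), ])$counts
  key <- c("bead_concentration", "plasmin_concentration")
  merged <- merge(a, b, by = key, all = TRUE)
  for (col in c("n_total", "n_cleaved", "n_uncleaved", "n_bundled")) {
    got <- rowSums(cbind(merged[[paste0(col, ".x")]],
                         merged[[paste0(col, ".y")]]), na.rm = TRUE)
    want <- t_all$counts[match(paste(merged[[1]], merged[[2]]),
                               paste(t_all$counts[[1]],
                                     t_all$counts[[2]])), col]
    expect_equal(got, want)
  }
})

test_that("empty denominators yield absent percentages, not zeros", {
  allclv <- make_cleaved(5, site = "length")
  tab <- tabulate_outcomes(allclv)
  expect_true(is.na(tab$percentages$pct_bundled_of_uncleaved))
  expect_true(is.na(tab$percentages$pct_elongated_of_bundled))
  expect_true(is.na(tab$percentages$pct_no_further_of_ridge))
})

test_that("box-whisker summaries follow the interpolated-quartile convention", {
  bw0 <- box_whisker(c(30, 30, 30))
  expect_equal(bw0$median, 30)
  expect_equal(bw0$iqr, 0)
  expect_equal(length(bw0$outliers), 0)

  v <- c(30, 60, 90, 120, 480)
  bw <- box_whisker(v)
  expect_equal(bw$q1, quartile_interp(v, 0.25))
  expect_equal(bw$q3, quartile_interp(v, 0.75))
  expect_equal(bw$median, quartile_interp(v, 0.5))
  # brute-force fence check decides the outlier status of 480
  fence_hi <- bw$q3 + 1.5 * bw$iqr
  expect_equal(480 %in% bw$outliers, 480 > fence_hi)
  expect_equal(bw$whisker_high, max(v[v <= fence_hi]))

  bw3 <- box_whisker(c(30, 30, 60))
  expect_equal(bw3$mean, 40)
  expect_equal(bw3$se, 10)

  expect_error(box_whisker(numeric(0)), "at least one")
})

test_that("box-whisker output is order-invariant with data-valued whiskers", {
  set.seed(23)
  for (i in 1:10) {
    v <- round(rexp(sample(3:40, 1), 1 / 60) / 30) * 30 + 30
    bw <- box_whisker(v)
    expect_identical(unclass(bw), unclass(box_whisker(rev(sort(v)))))
    expect_true(bw$whisker_low %in% v)
    expect_true(bw$whisker_high %in% v)
    expect_true(all(bw$outliers %in% v))
    expect_gte(bw$whisker_low, bw$q1 - 1.5 * bw$iqr)
    expect_lte(bw$whisker_high, bw$q3 + 1.5 * bw$iqr)
  }
})

test_that("two-group ANOVA matches hand computation and the t-test identity", {
  res <- two_group_test(c(1, 2, 3), c(4, 5, 6))
  # between SS = 13.5, within SS = 4 on df (1, 4)
  expect_equal(res$F, 13.5)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(round(res$p_value, 3), 0.021)

  same <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_false(same$degenerate)

  flat <- two_group_test(c(5, 5, 5), c(5, 5))
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)

  set.seed(24)
  for (i in 1:5) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), mean = 1)
    res <- two_group_test(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2)
    expect_equal(res$p_value, tt$p.value)
    expect_gte(res$F, 0)
    expect_true(res$p_value > 0 && res$p_value <= 1)
  }
})

test_that("ANOVA p agrees with a permutation oracle at moderate n", {
  set.seed(25)
  a <- rnorm(8); b <- rnorm(8, mean = 1.2)
  res <- two_group_test(a, b)
  y <- c(a, b)
  B <- 4000
  f_obs <- res$F
  f_perm <- replicate(B, {
    idx <- sample(16, 8)
    two_group_test(y[idx], y[-idx])$F
  })
  p_perm <- mean(f_perm >= f_obs)
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_perm - res$p_value), 3 * mc_se + 0.02)
})

test_that("concentration regression recovers closed-form OLS", {
  # perfectly collinear points on the linear scale (suppress lm's
  # perfect-fit warning)
  res <- suppressWarnings(
    regress_vs_concentration(c(1, 2, 3, 4), c(3, 5, 7, 9),
                             x_scale = "linear"))
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$r_squared, 1)

  res2 <- regress_vs_concentration(c(1, 2, 3), c(2, 4, 5),
                                   x_scale = "linear")
  expect_equal(res2$slope, 1.5)
  expect_equal(res2$intercept, 2 / 3)
  expect_equal(res2$p_value,
               summary(lm(c(2, 4, 5) ~ c(1, 2, 3)))$coefficients[2, 4])

  expect_error(regress_vs_concentration(c(1, 1, 1), c(1, 2, 3),
                                        x_scale = "linear"), "distinct")
  expect_error(regress_vs_concentration(c(1, 2), c(1, 2)), "3 observations")
  expect_error(regress_vs_concentration(c(-1, 1, 2), c(1, 2, 3)),
               "positive")
})

test_that("per-condition cleavage-time summaries use the frame rule", {
  rec <- bind_records(
    make_cleaved(3, frame = c(2L, 3L, 5L), bead = 1e9),
    make_cleaved(2, frame = c(2L, 2L), bead = 1e10))
  bw <- cleavage_time_summaries(rec)
  expect_named(bw, c("1e+09", "1e+10"))
  expect_equal(bw[["1e+09"]]$mean, mean(c(30, 60, 120)))
  expect_equal(bw[["1e+10"]]$median, 30)
  expect_equal(cleavage_time_summaries(make_uncleaved(3)), list())
})
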