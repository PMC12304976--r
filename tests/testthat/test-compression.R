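test_that("exact power laws give exact local slopes with zero SE", {
  cv <- power_law_curve(seq(10, 90, 5), s = 1 / 3)
  sl <- local_slopes(cv)
  expect_true(all(abs(sl$slope - 1 / 3) < 1e-10))
  expect_true(all(sl$se < 1e-10))
  expect_true(all(sl$retained))
  # triplets and quadruplets over 17 points: 15 + 14 windows
  expect_identical(nrow(sl), 29L)
  lin <- local_slopes(power_law_curve(seq(10, 90, 5), s = 1))
  expect_true(all(abs(lin$slope - 1) < 1e-10))
})

test_that("gate-failing points are excluded before windowing", {
  cv <- power_law_curve(seq(10, 90, 5), s = 1 / 3)
  cv$passed[1:3] <- FALSE
  sl <- local_slopes(cv)
  expect_identical(nrow(sl), (14L - 2L) + (14L - 3L))
  expect_true(all(sl$level_lo_db >= 25))
  cv$passed <- FALSE
  expect_error(local_slopes(cv), "insufficient")
})

test_that("noisy slope estimates agree with the normal-equations oracle", {
  set.seed(101)
  cv <- power_law_curve(seq(10, 90, 5), s = 1 / 3)
  cv$magnitude <- cv$magnitude * 10^rnorm(17, 0, 0.05)
  sl <- local_slopes(cv)
  x <- log10(cv$level_pa); y <- log10(cv$magnitude)
  k <- 1L
  for (np in 3:4) {
    for (i in seq_len(17 - np + 1)) {
      o <- oracle_ols(x[i:(i + np - 1)], y[i:(i + np - 1)])
      expect_equal(sl$slope[k], o$slope, tolerance = 1e-12)
      expect_equal(sl$se[k], o$se, tolerance = 1e-10)
      k <- k + 1L
    }
  }
  expect_true(all(sl$retained == (sl$se <= 0.15)))
})

test_that("per-segment minima are extracted with and without frequency windows", {
  est <- tibble::tibble(segment = 1L, freq = 1000,
                        slope = c(0.9, 0.41, 0.35, 0.98),
                        se = 0.01, retained = TRUE)
  expect_equal(min_slope(est)$min_slope, 0.35)
  # everything filtered out -> flagged empty
  est$retained <- FALSE
  m <- min_slope(est)
  expect_false(m$has_retained)
  expect_true(is.na(m$min_slope))
  # multi-frequency protocol: minimum window centers near the CF
  est2 <- tibble::tibble(
    segment = 1L,
    freq = rep(c(800, 1000, 1200, 2200), each = 3),
    slope = rep(c(0.9, 1 / 3, 0.8, 1.0), each = 3) + rep(c(-0.01, 0, 0.01), 4),
    se = 0.01, retained = TRUE)
  m2 <- min_slope(est2, freq_window = 500, freq_step = 10)
  expect_lt(abs(m2$freq - 1000), 500)
  expect_equal(m2$min_slope, 1 / 3 - 0.01)
})

test_that("cohort trends reproduce exact lines and match the OLS oracle", {
  exact <- tibble::tibble(segment = 1:5, freq = c(800, 1200, 1700, 2100, 2500),
                          min_slope = 1 / 3, se = 0, n_retained = 10L,
                          has_retained = TRUE)
  tr <- suppressWarnings(cohort_trend(exact))  # exact fit: lm warns
  expect_equal(tr$m, 0, tolerance = 1e-12)
  expect_equal(tr$q, 1 / 3, tolerance = 1e-12)
  expect_equal(tr$mean_min, 1 / 3)
  # collinear points recover the two-point line y = 1e-4 x + 0.2
  lin <- tibble::tibble(segment = 1:3, freq = c(1000, 1500, 2000),
                        min_slope = c(0.3, 0.35, 0.4), se = 0,
                        n_retained = 10L, has_retained = TRUE)
  tr2 <- suppressWarnings(cohort_trend(lin))
  expect_equal(tr2$m, 1e-4, tolerance = 1e-12)
  expect_equal(tr2$q, 0.2, tolerance = 1e-10)
  # random minima: m, q and CIs against the normal-equations oracle + lm
  set.seed(7)
  rnd <- tibble::tibble(segment = 1:20, freq = runif(20, 1000, 2500),
                        min_slope = 1 / 3 + rnorm(20, 0, 0.02), se = 0.01,
                        n_retained = 10L, has_retained = TRUE)
  tr3 <- cohort_trend(rnd)
  o <- oracle_ols(rnd$freq, rnd$min_slope)
  expect_equal(tr3$m, o$slope, tolerance = 1e-12)
  expect_equal(tr3$q, o$intercept, tolerance = 1e-12)
  td <- tidy(tr3)
  expect_identical(nrow(td), 2L)
  expect_equal(glance(tr3)$mean_min_slope, mean(rnd$min_slope))
})

test_that("sensitivity transform shifts log-log slopes by exactly one", {
  cv <- power_law_curve(seq(20, 80, 5), s = 1 / 3)
  sens <- sensitivity_curve(cv)
  sl <- local_slopes(sens)
  expect_true(all(abs(sl$slope - (-2 / 3)) < 1e-10))
  lin <- sensitivity_curve(power_law_curve(seq(20, 80, 5), s = 1))
  expect_true(all(abs(local_slopes(lin)$slope) < 1e-10))
  # round trip: A = S * P exactly
  expect_equal(sens$magnitude * sens$level_pa, sens$raw_magnitude)
})

hinge_curve <- function(levels_db, s1 = -2 / 3, bp_pa = 1, s_at = 1,
                        segment = 1L) {
  pa <- db_to_pa(levels_db)
  x <- log10(pa)
  y <- log10(s_at) + s1 * pmin(x - log10(bp_pa), 0)
  tibble::tibble(segment = segment, freq = 1000, level_db = levels_db,
                 level_pa = pa, magnitude = 10^y, rayleigh_p = 0,
                 n_reps = 20L, passed = TRUE)
}

test_that("piecewise fits recover exact hinge curves and flag flat ones", {
  # breakpoint at 74 dB SPL lies on the observed level grid
  cv <- hinge_curve(seq(10, 90, 4), bp_pa = db_to_pa(74))
  f <- piecewise_fit(cv)
  expect_true(f$compressive)
  expect_equal(f$s1, -2 / 3, tolerance = 1e-6)
  expect_equal(f$p_infl, log10(db_to_pa(74)), tolerance = 0.11)
  flat <- power_law_curve(seq(10, 90, 10), s = 0)
  ff <- piecewise_fit(flat)
  expect_false(ff$compressive)
  expect_true(is.na(tidy(ff)$s1))
})

test_that("noisy piecewise fits reach the brute-force grid-search RSS", {
  set.seed(55)
  cv <- hinge_curve(seq(10, 90, 5), bp_pa = db_to_pa(60))
  cv$magnitude <- cv$magnitude * 10^rnorm(17, 0, 0.05)
  f <- piecewise_fit(cv)
  oracle <- oracle_hinge_rss(log10(cv$level_pa), log10(cv$magnitude))
  expect_equal(f$rss, oracle, tolerance = 1e-10)
})

test_that("alignment is translation invariant and averages ideal curves exactly", {
  base <- hinge_curve(seq(10, 90, 4), bp_pa = db_to_pa(60))
  shifted <- base
  shifted$segment <- 2L
  shifted$level_pa <- base$level_pa * 10^0.35     # known (dx, dy) offset
  shifted$level_db <- pa_to_db(shifted$level_pa)
  shifted$magnitude <- base$magnitude * 10^(-0.35 * 2 / 3)
  al <- align_and_average(dplyr::bind_rows(base, shifted), bin_width = 0.05)
  expect_identical(al$n_curves, 2L)
  expect_true(all(al$average$sd_log_s < 1e-9, na.rm = TRUE))
  # averaged slopes: -2/3 in the compressive region, 0 above the inflection
  lo <- al$window_slopes[al$window_slopes$x < -0.3, ]
  hi <- al$window_slopes[al$window_slopes$x > 0.3, ]
  expect_true(all(abs(lo$slope + 2 / 3) < 1e-6))
  expect_true(all(abs(hi$slope) < 1e-6))
})

test_that("nonlinearity classification uses a strict 0.5 threshold", {
  est <- tibble::tibble(slope = 0.49, se = 0.01, retained = TRUE)
  expect_true(classify_nonlinear(est))
  est2 <- tibble::tibble(slope = c(0.5, 1.0), se = 0.01, retained = TRUE)
  expect_false(classify_nonlinear(est2))
  est3 <- tibble::tibble(slope = 0.2, se = 0.5, retained = FALSE)
  expect_error(classify_nonlinear(est3), "retained")
})

increment_curve <- function(increments) {
  x <- seq(0, by = 0.25, length.out = length(increments) + 1)
  y <- cumsum(c(0, increments * 0.25))
  tibble::tibble(level_pa = 10^x, magnitude = 10^y, passed = TRUE)
}

test_that("sublinear-run detection needs three consecutive shallow increments", {
  expect_true(sublinear_run_mask(increment_curve(c(0.3, 0.3, 0.3, 1.0))))
  expect_false(sublinear_run_mask(increment_curve(c(0.3, 1.2, 0.3, 1.2))))
  cube <- power_law_curve(seq(10, 60, 10), s = 1 / 3)
  expect_true(sublinear_run_mask(cube, slope_threshold = 0.4))
  expect_error(sublinear_run_mask(increment_curve(c(0.3, 0.3))[1:3, ]), "4")
})
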