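make_sine_bundle <- function(a = 1, freq = 100, fs = 2000, duration = 0.5,
                             n_reps = 5, noise = 0, seed = 1) {
  n <- fs * duration
  t <- (0:(n - 1)) / fs
  base <- a * cos(2 * pi * freq * t)
  set.seed(seed)
  reps <- matrix(rep(base, each = n_reps), nrow = n_reps) +
    matrix(rnorm(n_reps * n, 0, noise), nrow = n_reps)
  structure(list(reps = reps, fs = fs, duration = duration, n_reps = n_reps,
                 stimulus = tone_spec(freq, a), segment = NULL, seed = seed,
                 level_pa = a, level_db = NA_real_),
            class = "recording_bundle")
}

test_that("noiseless locked repetitions give exact magnitude and the corrected p", {
  b <- make_sine_bundle(a = 0.7, n_reps = 5)
  r <- extract_response(b, 100, alpha = 0.01)
  expect_equal(r$magnitude, 0.7, tolerance = 1e-9)
  expect_equal(r$phase, 0, tolerance = 1e-9)
  # perfect locking: Rbar = 1, Z = n, second-order corrected p; with only
  # five repetitions this sits just above the 0.001 microphonic criterion
  # but passes the 0.01 vibrometry criterion
  n <- 5
  expect_equal(r$rayleigh_p, exp(-n) * (1 + (2 * n - n^2) / (4 * n)),
               tolerance = 1e-12)
  expect_true(r$passed)
  expect_false(extract_response(b, 100, alpha = 0.001)$passed)
})

test_that("balanced phasors cancel and are not called phase locked", {
  rt <- rayleigh_test(c(0, 2 * pi / 3, 4 * pi / 3))
  expect_equal(rt$r_bar, 0, tolerance = 1e-12)
  expect_gt(rt$p_value, 0.9)
})

test_that("rayleigh p-values are uniform under the noise-only null", {
  ps <- vapply(1:400, function(i) {
    extract_response(noise_bundle(seed = 1000 + i), 1000)$rayleigh_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # gate specificity: pass rate matches alpha within binomial error
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("off-grid frequencies are refused rather than interpolated", {
  b <- make_sine_bundle()
  expect_error(extract_response(b, 100.3), "grid")
})

test_that("coherent averaging lowers the noise floor by sqrt(n_reps)", {
  floor_of <- function(n_reps) {
    b <- noise_bundle(seed = 5, n_reps = n_reps, fs = 4000, duration = 0.256)
    sp <- average_spectrum(b)
    stats::median(sp$magnitude[-1])
  }
  ratio <- floor_of(1) / floor_of(100)
  expect_gt(ratio, sqrt(100) * 0.6)
  expect_lt(ratio, sqrt(100) * 1.6)
})

test_that("averaged spectra obey Parseval and isolate grid-locked lines", {
  b <- make_sine_bundle(a = 1, n_reps = 1)
  sp <- average_spectrum(b)
  peak <- sp$magnitude[sp$freq == 100]
  expect_equal(peak, 1, tolerance = 1e-9)
  expect_lt(max(sp$magnitude[sp$freq != 100]), 1e-9)
  # Parseval: time-domain power equals summed one-sided spectral power
  pw_time <- mean(b$reps[1, ]^2)
  pw_spec <- sum((sp$magnitude / 2)^2 * 2) # amplitude -> power per line
  expect_equal(pw_spec, pw_time, tolerance = 1e-9)
})

test_that("distortion-product bins follow the combination-tone arithmetic", {
  dp <- hopfcochlea:::dp_frequencies(1230, 1236, max_order = 3)
  expect_setequal(dp$freq[dp$order == 3], c(1224, 1242))
  expect_setequal(dp$freq[dp$order == 5], c(1218, 1248))
})

test_that("a linear system produces no distortion products", {
  lev <- db_to_pa(c(50, 60, 70))
  bundles <- lapply(seq_along(lev), function(i)
    simulate_transducer_recording(tone_spec(c(1230, 1236), lev[i]),
                                  x_half = 1e6, gain = 1e5,
                                  noise_rms = 0.01, n_reps = 10, seed = i))
  rep <- measure_dps(bundles, 1230, 1236)
  dps <- rep$components[rep$components$role == "dp", ]
  expect_false(any(dps$passed))
  expect_true(all(is.na(rep$ratios$ratio)))
})

test_that("saturating-transducer distortion ratios rise with level", {
  lev <- db_to_pa(seq(50, 80, 5))
  x_half <- db_to_pa(78)
  bundles <- lapply(seq_along(lev), function(i)
    simulate_transducer_recording(tone_spec(c(1230, 1236), lev[i]),
                                  x_half = x_half, gain = 50,
                                  noise_rms = 0.005, n_reps = 20, seed = i))
  rep <- measure_dps(bundles, 1230, 1236)
  r <- rep$ratios$ratio
  expect_true(all(is.finite(r)))
  expect_true(all(diff(r) > 0))
})
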