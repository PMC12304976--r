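test_that("steady-state amplitude follows the cube-root law at criticality", {
  p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
  # at resonance and criticality F0 = |beta| A^3
  expect_equal(steady_state_amplitude(p, F0 = 8, omega = p$omega_c), 2,
               tolerance = 1e-9)
  rc <- response_curve_theory(p, p$omega_c, F0_grid = c(1, 8, 27))
  expect_equal(rc$amplitude, c(1, 2, 3), tolerance = 1e-9)
  # zero forcing, stable origin
  expect_equal(steady_state_amplitude(p, 0, p$omega_c), 0)
})

test_that("response becomes linear far from the characteristic frequency", {
  p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
  A <- steady_state_amplitude(p, F0 = 1, omega = p$omega_c + 1e3)
  expect_equal(A, 1e-3, tolerance = 1e-3)
})

test_that("steady-state solver agrees with a dense grid-search oracle", {
  p <- hopf_params(epsilon = -0.5, omega_c = 2 * pi * 500,
                   beta_re = 1, beta_im = 0.3)
  A <- steady_state_amplitude(p, F0 = 0.7, omega = p$omega_c + 2)
  expect_equal(A, oracle_steady_amplitude(-0.5, 1, 0.3, 2, 0.7),
               tolerance = 1e-5)
})

test_that("steady-state amplitude is monotone nondecreasing in forcing", {
  set.seed(11)
  for (i in 1:20) {
    p <- hopf_params(epsilon = -runif(1, 0, 5), omega_c = 2 * pi * 800,
                     beta_re = runif(1, 0.5, 2), beta_im = runif(1, -1, 1))
    grid <- sort(10^runif(8, -2, 2))
    A <- steady_state_amplitude(p, grid, p$omega_c + runif(1, -50, 50))
    expect_true(all(diff(A) >= -1e-12))
  }
})

test_that("log-log slopes of the critical resonant curve hit 1/3 and -2/3", {
  p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
  F0 <- 10^seq(-1, 1.5, by = 0.1)           # 2.5 decades
  rc <- response_curve_theory(p, p$omega_c, F0)
  s <- oracle_ols(log10(rc$F0), log10(rc$amplitude))$slope
  expect_gte(s, 0.330); expect_lte(s, 0.337)
  sens <- rc$amplitude / rc$F0
  s2 <- oracle_ols(log10(rc$F0), log10(sens))$slope
  expect_equal(s2, -2 / 3, tolerance = 0.01)
  # linear limit: detuning so large the cubic term stays below 1%
  A_lin <- steady_state_amplitude(p, F0 = 10^seq(-3, -1, 0.25),
                                  omega = p$omega_c + 1e4)
  s3 <- oracle_ols(seq(-3, -1, 0.25), log10(A_lin))$slope
  expect_gte(s3, 0.99); expect_lte(s3, 1.01)
})

test_that("free dynamics decay below criticality and cycle above it", {
  p <- hopf_params(epsilon = -1, omega_c = 2 * pi * 10)
  tr <- integrate_oscillator(p, forcing_spec(numeric(0), numeric(0)),
                             duration = 20, fs = 400, z0 = 1 + 0i)
  expect_lt(Mod(tr$z[length(tr$z)]), 1e-6)
  # spontaneous side: limit cycle radius sqrt(epsilon / beta_re)
  p2 <- hopf_params(epsilon = 0.04, omega_c = 2 * pi * 100)
  tr2 <- integrate_oscillator(p2, forcing_spec(numeric(0), numeric(0)),
                              duration = 300, fs = 2000, z0 = 0.01 + 0i)
  expect_equal(trajectory_amplitude(tr2, discard = 0.9), 0.2,
               tolerance = 0.01)
})

test_that("integrator reaches the analytic steady state under forcing", {
  p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 50)
  tr <- integrate_oscillator(p, forcing_spec(8, p$omega_c),
                             duration = 5, fs = 2000)
  expect_equal(trajectory_amplitude(tr, discard = 0.5), 2, tolerance = 0.01)
})

test_that("integrated steady amplitudes match the root solver across random draws", {
  set.seed(42)
  for (i in 1:12) {
    eps <- -runif(1, 0.2, 2)
    p <- hopf_params(epsilon = eps, omega_c = 2 * pi * 100,
                     beta_re = runif(1, 0.5, 2), beta_im = runif(1, -0.5, 0.5))
    dw <- runif(1, -20, 20)
    F0 <- 10^runif(1, -1, 1)
    target <- steady_state_amplitude(p, F0, p$omega_c + dw)
    tr <- integrate_oscillator(p, forcing_spec(F0, p$omega_c + dw),
                               duration = 30, fs = 1000)
    expect_equal(trajectory_amplitude(tr, discard = 0.7), target,
                 tolerance = 0.01)
  }
})

test_that("deterministic trajectories ignore the seed, noisy ones honor it", {
  p <- hopf_params(epsilon = -0.5, omega_c = 2 * pi * 20)
  f <- forcing_spec(1, p$omega_c)
  a <- integrate_oscillator(p, f, 1, 400, seed = 1)
  b <- integrate_oscillator(p, f, 1, 400, seed = 99)
  expect_identical(a$z, b$z)
  pn <- hopf_params(epsilon = -0.5, omega_c = 2 * pi * 20, noise_sigma = 0.1)
  n1 <- integrate_oscillator(pn, f, 1, 400, seed = 7)
  n2 <- integrate_oscillator(pn, f, 1, 400, seed = 7)
  n3 <- integrate_oscillator(pn, f, 1, 400, seed = 8)
  expect_identical(n1$z, n2$z)
  expect_false(identical(n1$z, n3$z))
})

test_that("divergence guard trips when the state escapes its bound", {
  # spontaneous oscillation toward a limit cycle of radius sqrt(5) > bound
  p <- hopf_params(epsilon = 5, omega_c = 2 * pi * 10)
  expect_error(
    integrate_oscillator(p, forcing_spec(numeric(0), numeric(0)),
                         duration = 50, fs = 400, z0 = 1 + 0i, bound = 1.5),
    "diverged")
})

test_that("sigmoid transducer is odd, bounded, and linear for small signals", {
  expect_identical(sigmoid_transducer(0, 1), 0)
  x <- seq(-5, 5, 0.1)
  expect_true(all(abs(sigmoid_transducer(x, 2)) < 1))
  expect_equal(sigmoid_transducer(x, 2), -sigmoid_transducer(-x, 2))
  xs <- 0.001 * sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(sigmoid_transducer(xs, 1), xs, tolerance = 1e-6)
  expect_error(sigmoid_transducer(x, -1), "x_half")
})

test_that("transducer cubic distortion matches the tanh Taylor coefficient", {
  # tanh(u) = u - u^3/3 + ...; for u = A(cos t1 + cos t2) the 2f1-f2 line
  # has amplitude (1/3)(3/4) A^3 = A^3/4
  fs <- 8000; dur <- 1
  f1 <- 100; f2 <- 110
  a <- 0.05; x_half <- 1
  t <- (0:(fs * dur - 1)) / fs
  y <- sigmoid_transducer(a * cos(2 * pi * f1 * t) + a * cos(2 * pi * f2 * t),
                          x_half)
  sp <- Mod(stats::fft(y)) * 2 / length(y)
  dp_amp <- sp[(2 * f1 - f2) * dur + 1]
  expect_equal(dp_amp, (a / x_half)^3 / 4, tolerance = 0.01)
})
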