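#' Parameters of a Hopf oscillator
#'
#' Bundles the normal-form parameters of a (possibly noisy) Hopf oscillator
#' \deqn{\dot z = (\epsilon + i\omega_c) z - \beta |z|^2 z,}
#' the canonical model of a cochlear segment operating near a Hopf
#' bifurcation. For `epsilon <= 0` the quiescent state is stable and driven
#' responses are unique; for `epsilon > 0` the oscillator runs spontaneously
#' on a limit cycle of radius `sqrt(epsilon / beta_re)`.
#'
#' @param epsilon Control parameter (1/s). `epsilon <= 0` is the healthy
#'   quiescent side; `epsilon > 0` oscillates spontaneously.
#' @param omega_c Natural angular frequency (rad/s), `2 * pi * CF`.
#' @param beta_re Real part of the cubic coefficient; must be positive so the
#'   cubic term is stabilizing.
#' @param beta_im Imaginary part of the cubic coefficient.
#' @param noise_sigma Intensity of additive white noise on the state
#'   (state-units per sqrt(s)); `0` gives deterministic dynamics.
#' @return An object of class `hopf_params`.
#' @examples
#' hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
#' @export
hopf_params <- function(epsilon = 0, omega_c = 2 * pi * 1000,
                        beta_re = 1, beta_im = 0, noise_sigma = 0) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (!is.numeric(omega_c) || length(omega_c) != 1L || omega_c <= 0)
    stop("`omega_c` must be a positive scalar (rad/s)", call. = FALSE)
  if (!is.numeric(beta_re) || length(beta_re) != 1L || beta_re <= 0)
    stop("`beta_re` must be > 0: the cubic term must be stabilizing",
         call. = FALSE)
  stopifnot(is.numeric(beta_im), length(beta_im) == 1L)
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0)
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(
    list(epsilon = epsilon, omega_c = omega_c,
         beta_re = beta_re, beta_im = beta_im, noise_sigma = noise_sigma),
    class = "hopf_params"
  )
}

#' @export
print.hopf_params <- function(x, ...) {
  cat("<hopf_params>\n")
  cat(sprintf("  epsilon: %g 1/s (%s)\n", x$epsilon,
              if (x$epsilon > 0) "spontaneous" else "quiescent"))
  cat(sprintf("  omega_c: %g rad/s (CF = %g Hz)\n", x$omega_c,
              x$omega_c / (2 * pi)))
  cat(sprintf("  beta:    %g %+gi\n", x$beta_re, x$beta_im))
  cat(sprintf("  noise:   %g\n", x$noise_sigma))
  invisible(x)
}

#' Sinusoidal forcing specification
#'
#' One or more rotating-wave forcing components
#' \eqn{F_k e^{i(\omega_k t + \phi_k)}} applied to a Hopf oscillator.
#'
#' @param amplitude Forcing amplitudes (oscillator-forcing units, >= 0).
#' @param omega Angular frequencies (rad/s, > 0, distinct).
#' @param phase Phases (rad); recycled to the length of `amplitude`.
#' @return A tibble of class `forcing_spec` with columns `amplitude`,
#'   `omega`, `phase`.
#' @examples
#' forcing_spec(amplitude = 8, omega = 2 * pi * 1000)
#' @export
forcing_spec <- function(amplitude, omega, phase = 0) {
  stopifnot(is.numeric(amplitude), is.numeric(omega), is.numeric(phase))
  if (any(amplitude < 0)) stop("forcing amplitudes must be >= 0", call. = FALSE)
  if (any(omega <= 0)) stop("forcing frequencies must be > 0", call. = FALSE)
  if (anyDuplicated(omega)) stop("forcing frequencies must be distinct",
                                 call. = FALSE)
  out <- tibble::tibble(amplitude = amplitude, omega = omega,
                        phase = rep_len(phase, length(amplitude)))
  class(out) <- c("forcing_spec", class(out))
  out
}

# |response| -> |forcing| relation of the forced Hopf steady state:
# F0(A)^2 = (beta_re A^3 - eps A)^2 + (A (omega - omega_c) + beta_im A^3)^2
forcing_for_amplitude <- function(params, A, omega) {
  dw <- omega - params$omega_c
  sqrt((params$beta_re * A^3 - params$epsilon * A)^2 +
         (A * dw + params$beta_im * A^3)^2)
}

#' Steady-state amplitude of a driven Hopf oscillator
#'
#' Solves the steady-state amplitude relation of the sinusoidally forced Hopf
#' normal form,
#' \deqn{F_0^2 = (\beta_{re} A^3 - \epsilon A)^2 +
#'   (A(\omega - \omega_c) + \beta_{im} A^3)^2,}
#' for the response amplitude `A`. On the quiescent side (`epsilon <= 0`) the
#' physical root is unique; the solver brackets it and refines to a relative
#' tolerance of 1e-10. At criticality (`epsilon = 0`) and resonance the
#' amplitude follows the compressive cube-root law `A = (F0 / |beta|)^(1/3)`;
#' far from resonance it is linear, `A = F0 / |omega - omega_c|`.
#'
#' @param params A [hopf_params()] object with `epsilon <= 0`.
#' @param F0 Forcing amplitude(s), >= 0 (vectorized).
#' @param omega Drive angular frequency (rad/s).
#' @return Numeric vector of nonnegative steady-state amplitudes.
#' @examples
#' p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
#' steady_state_amplitude(p, F0 = 8, omega = p$omega_c) # exactly 2
#' @export
steady_state_amplitude <- function(params, F0, omega) {
  stopifnot(inherits(params, "hopf_params"))
  if (params$epsilon > 0)
    stop("steady_state_amplitude() requires epsilon <= 0 (unique branch); ",
         "use integrate_oscillator() on the spontaneous side", call. = FALSE)
  if (any(F0 < 0)) stop("`F0` must be >= 0", call. = FALSE)
  stopifnot(is.numeric(omega), length(omega) == 1L, omega > 0)
  vapply(F0, function(f) {
    if (f == 0) return(0)
    # forcing_for_amplitude() is strictly increasing in A for epsilon <= 0,
    # so bracket [0, upper] and bisect via uniroot
    upper <- max((f / params$beta_re)^(1 / 3), 1e-12)
    while (forcing_for_amplitude(params, upper, omega) < f) upper <- 2 * upper
    g <- function(a) forcing_for_amplitude(params, a, omega) - f
    r <- stats::uniroot(g, interval = c(0, upper),
                        tol = 1e-10 * max(upper, 1e-3))
    if (!is.finite(r$root)) stop("no real steady-state root found",
                                 call. = FALSE)
    r$root
  }, numeric(1))
}

# Complex steady-state response z = A exp(i(omega t + phi_F + phi)):
# phi = -Arg(A(-eps + i(omega - omega_c)) + beta A^3) relative to the forcing
steady_state_phasor <- function(params, F0, omega, phase = 0) {
  A <- steady_state_amplitude(params, F0, omega)
  dw <- omega - params$omega_c
  denom <- complex(real = -params$epsilon * A + params$beta_re * A^3,
                   imaginary = A * dw + params$beta_im * A^3)
  phi <- ifelse(A > 0, -Arg(denom), 0)
  complex(modulus = A, argument = phase + phi)
}

#' Theoretical forcing-response curve
#'
#' Evaluates [steady_state_amplitude()] over a grid of forcing amplitudes.
#'
#' @inheritParams steady_state_amplitude
#' @param F0_grid Strictly increasing nonnegative forcing amplitudes.
#' @return A tibble with columns `F0` and `amplitude`; amplitudes are
#'   monotone nondecreasing in `F0`.
#' @examples
#' p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
#' response_curve_theory(p, omega = p$omega_c, F0_grid = c(1, 8, 27))
#' @export
response_curve_theory <- function(params, omega, F0_grid) {
  if (length(F0_grid) == 0L) stop("`F0_grid` must be nonempty", call. = FALSE)
  if (is.unsorted(F0_grid, strictly = TRUE))
    stop("`F0_grid` must be strictly increasing", call. = FALSE)
  tibble::tibble(F0 = F0_grid,
                 amplitude = steady_state_amplitude(params, F0_grid, omega))
}

#' Integrate a (stochastic) forced Hopf oscillator
#'
#' Time-domain integration of
#' \deqn{\dot z = (\epsilon + i\omega_c) z - \beta|z|^2 z +
#'   \sum_k F_k e^{i(\omega_k t + \phi_k)} (+ \sigma\,\xi(t)),}
#' with a fixed-step classical Runge-Kutta scheme when `noise_sigma = 0` and
#' Euler-Maruyama at the same step otherwise. The integrator internally
#' oversamples so that `omega * dt` stays small, and records the state on the
#' requested sampling grid. Deterministic given `seed`; with
#' `noise_sigma = 0` the result does not depend on `seed`.
#'
#' @param params A [hopf_params()] object.
#' @param forcing A [forcing_spec()] (may have zero rows for free dynamics).
#' @param duration Integration time (s, > 0).
#' @param fs Sampling rate (Hz); must exceed 4x the highest forcing frequency.
#' @param z0 Initial state (complex scalar).
#' @param seed Integer seed for the noise path (ignored when noiseless).
#' @param bound Divergence guard: integration aborts if `|z|` exceeds it.
#' @return A `hopf_trajectory`: list with `t`, `z` (complex), `fs`, `seed`.
#' @examples
#' p <- hopf_params(epsilon = -1, omega_c = 2 * pi * 10)
#' tr <- integrate_oscillator(p, forcing_spec(numeric(0), numeric(0)),
#'                            duration = 2, fs = 400, z0 = 1 + 0i)
#' @export
integrate_oscillator <- function(params, forcing, duration, fs,
                                 z0 = 0 + 0i, seed = NULL, bound = 1e6) {
  stopifnot(inherits(params, "hopf_params"))
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be > 0", call. = FALSE)
  if (nrow(forcing) > 0 && fs <= 4 * max(forcing$omega) / (2 * pi))
    stop("`fs` must exceed 4x the highest forcing frequency", call. = FALSE)
  n <- round(duration * fs)
  dt <- 1 / fs
  w_max <- max(params$omega_c, if (nrow(forcing) > 0) forcing$omega else 0)
  oversample <- max(1L, ceiling(w_max * dt / 0.15))
  noise <- numeric(0)
  if (params$noise_sigma > 0) {
    if (!is.null(seed)) {
      noise <- local_seed_rnorm(seed, 2L * n * oversample)
    } else {
      noise <- stats::rnorm(2L * n * oversample)
    }
    noise <- noise * params$noise_sigma * sqrt(dt / oversample)
  }
  zz <- hopf_integrate_cpp(params$epsilon, params$omega_c,
                           params$beta_re, params$beta_im,
                           forcing$amplitude, forcing$omega, forcing$phase,
                           dt, n, oversample, Re(z0), Im(z0), noise, bound)
  structure(
    list(t = seq(0, by = dt, length.out = n + 1L),
         z = complex(real = zz[, 1], imaginary = zz[, 2]),
         fs = fs, seed = seed),
    class = "hopf_trajectory"
  )
}

#' @export
print.hopf_trajectory <- function(x, ...) {
  cat(sprintf("<hopf_trajectory> %d samples at %g Hz (%.3g s)\n",
              length(x$z), x$fs, length(x$z) / x$fs))
  invisible(x)
}

#' Steady-state amplitude of a trajectory
#'
#' Mean modulus of the state over the trailing fraction of a trajectory,
#' after discarding the leading transient.
#'
#' @param trajectory A `hopf_trajectory`.
#' @param discard Leading fraction to drop (default 0.5).
#' @return Scalar amplitude estimate.
#' @export
trajectory_amplitude <- function(trajectory, discard = 0.5) {
  stopifnot(inherits(trajectory, "hopf_trajectory"),
            discard >= 0, discard < 1)
  z <- trajectory$z
  keep <- seq.int(floor(length(z) * discard) + 1L, length(z))
  mean(Mod(z[keep]))
}

#' Memoryless saturating transducer
#'
#' The stationary-nonlinearity null model: a hair-cell-like sigmoidal
#' (hyperbolic tangent) transduction curve `y = tanh(x / x_half)`. Unlike a
#' critical Hopf oscillator, this memoryless saturation imposes no power-law
#' floor on response growth, and its cubic distortion products grow
#' superlinearly with the primaries.
#'
#' @param x Input waveform (numeric vector).
#' @param x_half Half-saturation scale (> 0).
#' @return Waveform of the same length, bounded in (-1, 1).
#' @examples
#' sigmoid_transducer(seq(-3, 3, 0.5), x_half = 1)
#' @export
sigmoid_transducer <- function(x, x_half) {
  if (!is.numeric(x_half) || length(x_half) != 1L || x_half <= 0)
    stop("`x_half` must be a positive scalar", call. = FALSE)
  tanh(x / x_half)
}

# draw rnorm under a private RNG state (restores the caller's stream)
local_seed_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}
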