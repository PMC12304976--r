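#' Configuration of a synthetic cochlear segment
#'
#' Describes one simulated "cochlear segment": an active Hopf oscillator
#' tuned to a characteristic frequency plus a passive linear pathway, read
#' out as a microphonic-like scalar observable with additive measurement
#' noise,
#' \deqn{v(t) = g_{obs}\,\mathrm{Re}\,z(t)\,[EP\ on] + g_{pass}\,p(t) +
#'   \eta(t).}
#' The active path is forced by `F_k = coupling * P_k` for each stimulus tone
#' of pressure amplitude `P_k`. Switching `ep_on = FALSE` emulates abolishing
#' the endocochlear potential: the active path is removed entirely and only
#' the passive, linear pathway (plus noise) remains.
#'
#' @param cf Characteristic frequency (Hz); segments outside the 600--3300 Hz
#'   range covered by the middle-turn preparations raise a warning.
#' @param epsilon Hopf control parameter (1/s, <= 0 near criticality for a
#'   healthy segment).
#' @param beta_re,beta_im Cubic coefficient of the normal form.
#' @param coupling Forcing units per Pa of stimulus pressure.
#' @param passive_gain Observable units per Pa (passive linear path).
#' @param passive_phase Phase of the passive pathway relative to the
#'   stimulus (rad). The default quadrature offset (`pi/2`) reflects that
#'   the two generation mechanisms are not phase aligned, and reproduces the
#'   sharp transition between the compressive and passive-linear regimes
#'   seen in segment recordings; in-phase addition (`0`) smears the
#'   crossover over tens of dB.
#' @param obs_gain Observable units per oscillator state unit.
#' @param noise_rms Additive measurement noise, RMS per sample, in observable
#'   units.
#' @param ep_on Logical: endocochlear potential present (active path on)?
#' @param osc_noise Intensity of state noise inside the oscillator (usually
#'   0: repetitions then differ only in measurement noise).
#' @param seed Integer seed for the segment's noise realizations.
#' @return An object of class `segment_config`.
#' @examples
#' segment_config(cf = 1500, epsilon = -5)
#' @export
segment_config <- function(cf, epsilon, beta_re = 1, beta_im = 0,
                           coupling = 1.25e4, passive_gain = 50,
                           passive_phase = pi / 2,
                           obs_gain = 1, noise_rms = 100,
                           ep_on = TRUE, osc_noise = 0, seed = 1) {
  stopifnot(is.numeric(cf), length(cf) == 1L, cf > 0)
  if (cf < 600 || cf > 3300)
    warning("cf outside the 600-3300 Hz range of the emulated preparations",
            call. = FALSE)
  if (coupling <= 0 || obs_gain <= 0)
    stop("`coupling` and `obs_gain` must be > 0", call. = FALSE)
  if (noise_rms < 0) stop("`noise_rms` must be >= 0", call. = FALSE)
  structure(
    list(cf = cf, epsilon = epsilon, beta_re = beta_re, beta_im = beta_im,
         coupling = coupling, passive_gain = passive_gain,
         passive_phase = passive_phase,
         obs_gain = obs_gain, noise_rms = noise_rms,
         ep_on = isTRUE(ep_on), osc_noise = osc_noise,
         seed = as.integer(seed)),
    class = "segment_config"
  )
}

#' @export
print.segment_config <- function(x, ...) {
  cat(sprintf(
    "<segment_config> CF %g Hz, epsilon %g, EP %s, noise %g\n",
    x$cf, x$epsilon, if (x$ep_on) "on" else "off", x$noise_rms))
  invisible(x)
}

# default settling time before the analysis window opens
default_transient <- function(segment) {
  cycles <- 10 / segment$cf
  if (segment$epsilon < 0)
    max(cycles, min(5 / abs(segment$epsilon), 1))
  else
    50 / segment$cf
}

#' Simulate a repeated-presentation recording
#'
#' Drives a synthetic cochlear segment with a (multi)tone stimulus, discards
#' the onset transient, and returns `n_reps` repetitions of the steady-state
#' observable. Repetitions share the same underlying response and differ
#' only in the measurement-noise realization (per-repetition noise is drawn
#' deterministically from the segment seed), emulating repeated phase-locked
#' presentations of the same stimulus.
#'
#' @param segment A [segment_config()].
#' @param tones A [tone_spec()] tibble (levels in Pa). All frequencies must
#'   be grid locked: `freq * duration` integer.
#' @param n_reps Number of repetitions.
#' @param fs Sampling rate (Hz).
#' @param duration Analysis-window duration (s).
#' @param transient Settling time discarded before the window (s); default
#'   derived from `cf` and `epsilon`.
#' @return A `recording_bundle`: list with `reps` (`n_reps` x `n_samples`
#'   matrix), `fs`, `duration`, `n_reps`, `stimulus`, `segment`, `seed`,
#'   `level_pa`, `level_db`.
#' @examples
#' seg <- segment_config(cf = 1000, epsilon = -5, noise_rms = 0)
#' b <- simulate_recording(seg, tone_spec(1000, db_to_pa(60)),
#'                         n_reps = 4, fs = 8000, duration = 0.25)
#' @export
simulate_recording <- function(segment, tones, n_reps = 20,
                               fs = 16000, duration = 0.5, transient = NULL) {
  stopifnot(inherits(segment, "segment_config"), is.data.frame(tones))
  cyc <- tones$freq * duration
  if (any(abs(cyc - round(cyc)) > 1e-9))
    stop("stimulus frequencies must be grid locked to the analysis window",
         call. = FALSE)
  if (is.null(transient)) transient <- default_transient(segment)
  n <- round(duration * fs)
  n_tr <- ceiling(transient * fs)
  params <- hopf_params(epsilon = segment$epsilon,
                        omega_c = 2 * pi * segment$cf,
                        beta_re = segment$beta_re, beta_im = segment$beta_im,
                        noise_sigma = segment$osc_noise)
  t0 <- (n_tr + 1) / fs   # absolute time at which the analysis window opens
  base <- numeric(n)
  if (segment$ep_on && nrow(tones) > 0) {
    # phase-shift the forcing so tone phases refer to the window start
    forcing <- forcing_spec(amplitude = segment$coupling * tones$level,
                            omega = 2 * pi * tones$freq,
                            phase = tones$phase - 2 * pi * tones$freq * t0)
    tr <- integrate_oscillator(params, forcing,
                               duration = (n_tr + n) / fs, fs = fs,
                               seed = segment$seed)
    base <- base + segment$obs_gain * Re(tr$z[(n_tr + 2):(n_tr + n + 1)])
  } else if (segment$ep_on) {
    tr <- integrate_oscillator(params, forcing_spec(numeric(0), numeric(0)),
                               duration = (n_tr + n) / fs, fs = fs,
                               seed = segment$seed)
    base <- base + segment$obs_gain * Re(tr$z[(n_tr + 2):(n_tr + n + 1)])
  }
  t_win <- (seq_len(n) - 1) / fs   # window-local time base
  p <- numeric(n)
  for (i in seq_len(nrow(tones)))
    p <- p + tones$level[i] *
      cos(2 * pi * tones$freq[i] * t_win + tones$phase[i] +
            segment$passive_phase)
  base <- base + segment$passive_gain * p
  reps <- matrix(rep(base, each = n_reps), nrow = n_reps)
  if (segment$noise_rms > 0)
    reps <- reps + matrix(
      local_seed_rnorm(segment$seed, n_reps * n) * segment$noise_rms,
      nrow = n_reps)
  level_pa <- if (nrow(tones) > 0) max(tones$level) else 0
  structure(
    list(reps = reps, fs = fs, duration = duration, n_reps = n_reps,
         stimulus = tones, segment = segment, seed = segment$seed,
         level_pa = level_pa,
         level_db = if (level_pa > 0) pa_to_db(level_pa) else NA_real_),
    class = "recording_bundle"
  )
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> %d reps x %d samples at %g Hz\n",
              nrow(x$reps), ncol(x$reps), x$fs))
  if (nrow(x$stimulus) > 0)
    cat("  stimulus:", paste0(x$stimulus$freq, " Hz", collapse = ", "),
        sprintf("(max %.3g Pa)\n", x$level_pa))
  invisible(x)
}

#' Simulate a saturating-transducer recording
#'
#' The stationary-nonlinearity null: the stimulus pressure is passed through
#' a memoryless sigmoidal transducer ([sigmoid_transducer()]) instead of a
#' Hopf oscillator, plus measurement noise. Used to contrast the
#' level-independent distortion-product ratios of a critical oscillator with
#' the superlinearly growing distortion of a static saturation.
#'
#' @inheritParams simulate_recording
#' @param x_half Half-saturation pressure of the transducer (Pa).
#' @param gain Observable units per (dimensionless) transducer output.
#' @param noise_rms Measurement noise RMS per sample.
#' @param seed Integer seed.
#' @return A `recording_bundle`.
#' @export
simulate_transducer_recording <- function(tones, x_half, gain = 1,
                                          noise_rms = 0, n_reps = 20,
                                          fs = 16000, duration = 0.5,
                                          seed = 1) {
  stopifnot(is.data.frame(tones))
  cyc <- tones$freq * duration
  if (any(abs(cyc - round(cyc)) > 1e-9))
    stop("stimulus frequencies must be grid locked to the analysis window",
         call. = FALSE)
  n <- round(duration * fs)
  t_win <- (seq_len(n) - 1) / fs
  p <- numeric(n)
  for (i in seq_len(nrow(tones)))
    p <- p + tones$level[i] *
      cos(2 * pi * tones$freq[i] * t_win + tones$phase[i])
  base <- gain * sigmoid_transducer(p, x_half)
  reps <- matrix(rep(base, each = n_reps), nrow = n_reps)
  if (noise_rms > 0)
    reps <- reps + matrix(local_seed_rnorm(seed, n_reps * n) * noise_rms,
                          nrow = n_reps)
  level_pa <- if (nrow(tones) > 0) max(tones$level) else 0
  structure(
    list(reps = reps, fs = fs, duration = duration, n_reps = n_reps,
         stimulus = tones, segment = NULL, seed = seed,
         level_pa = level_pa,
         level_db = if (level_pa > 0) pa_to_db(level_pa) else NA_real_),
    class = "recording_bundle"
  )
}

#' Specification of a synthetic cohort
#'
#' Parameterizes a cohort of simulated cochlear segments, each probed with an
#' at-CF (and optionally off-CF) single-tone level series. Defaults emulate
#' the study conditions: characteristic frequencies spread over the
#' middle-turn range, near-critical control parameters drawn log-uniformly
#' from a small negative interval, a 10--90 dB SPL level series in 5 dB
#' steps, and 20 phase-locked repetitions per condition.
#'
#' @param n_segments Number of segments.
#' @param cf_range Characteristic-frequency range (Hz); CFs are drawn
#'   uniformly on the FFT grid within it.
#' @param levels_db Strictly increasing stimulus levels (dB SPL).
#' @param n_reps Repetitions per condition.
#' @param fs Sampling rate (Hz).
#' @param duration Analysis-window duration (s).
#' @param off_cf_offset Optional off-CF probe offset (Hz) added to each CF
#'   for a second, off-resonance level series; `NULL` for at-CF only.
#' @param ep_on Endocochlear potential on (active path present)?
#' @param epsilon_ratio_range Range of `|epsilon| / omega_c` for the healthy
#'   near-critical prior (log-uniform, applied with negative sign).
#' @param noise_rms,coupling,passive_gain,obs_gain Passed to
#'   [segment_config()].
#' @param master_seed Integer master seed; everything downstream is
#'   deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_segments = 20, cf_range = c(1000, 2500),
                        levels_db = seq(10, 90, by = 5), n_reps = 20,
                        fs = 16000, duration = 0.5, off_cf_offset = NULL,
                        ep_on = TRUE, epsilon_ratio_range = c(1e-5, 1e-4),
                        noise_rms = 100, coupling = 1.25e4,
                        passive_gain = 50, obs_gain = 1, master_seed = 1) {
  stopifnot(n_segments >= 1, length(cf_range) == 2, cf_range[2] > cf_range[1])
  if (is.unsorted(levels_db, strictly = TRUE))
    stop("`levels_db` must be strictly increasing", call. = FALSE)
  structure(
    list(n_segments = as.integer(n_segments), cf_range = cf_range,
         levels_db = levels_db, n_reps = as.integer(n_reps), fs = fs,
         duration = duration, off_cf_offset = off_cf_offset,
         ep_on = isTRUE(ep_on), epsilon_ratio_range = epsilon_ratio_range,
         noise_rms = noise_rms, coupling = coupling,
         passive_gain = passive_gain, obs_gain = obs_gain,
         master_seed = as.integer(master_seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort of cochlear segments
#'
#' Draws per-segment characteristic frequencies and near-critical control
#' parameters from a [cohort_spec()], simulates every (frequency, level)
#' condition, and (by default) immediately reduces each recording to its
#' Rayleigh-gated phasor response, returning tidy response curves ready for
#' [local_slopes()]. Fully deterministic given `master_seed`.
#'
#' @param spec A [cohort_spec()].
#' @param keep `"curves"` (default) stores only extracted response curves;
#'   `"bundles"` additionally retains the raw recording bundles (memory
#'   heavy; intended for small cohorts).
#' @param alpha Rayleigh gate level for curve extraction.
#' @return An object of class `hopf_cohort`: list with `spec`, `configs` (one
#'   row per segment: cf, epsilon, seed), `curves` (tibble: one row per
#'   segment x frequency x level) and, when requested, `bundles`.
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_spec(n_segments = 2, levels_db = seq(30, 80, 10),
#'                                   fs = 8000, duration = 0.25, n_reps = 5))
#' }
#' @export
generate_cohort <- function(spec, keep = c("curves", "bundles"),
                            alpha = 0.001) {
  stopifnot(inherits(spec, "cohort_spec"))
  keep <- match.arg(keep)
  grid <- 1 / spec$duration
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$master_seed)
  cf_lo <- ceiling(spec$cf_range[1] / grid)
  cf_hi <- floor(spec$cf_range[2] / grid)
  cfs <- sample(seq.int(cf_lo, cf_hi), spec$n_segments, replace = TRUE) * grid
  lr <- log(spec$epsilon_ratio_range)
  eps_ratio <- exp(stats::runif(spec$n_segments, lr[1], lr[2]))
  seeds <- sample.int(.Machine$integer.max - 1L, spec$n_segments)
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())

  configs <- tibble::tibble(
    segment = seq_len(spec$n_segments), cf = cfs,
    epsilon = -eps_ratio * 2 * pi * cfs, seed = seeds)
  levels_pa <- db_to_pa(spec$levels_db)
  curves <- list()
  bundles <- if (keep == "bundles") list() else NULL
  for (s in seq_len(spec$n_segments)) {
    seg <- segment_config(cf = configs$cf[s], epsilon = configs$epsilon[s],
                          coupling = spec$coupling,
                          passive_gain = spec$passive_gain,
                          obs_gain = spec$obs_gain,
                          noise_rms = spec$noise_rms,
                          ep_on = spec$ep_on, seed = configs$seed[s])
    freqs <- configs$cf[s]
    if (!is.null(spec$off_cf_offset))
      freqs <- c(freqs, round((configs$cf[s] + spec$off_cf_offset) / grid) * grid)
    for (f in freqs) {
      rows <- purrr::map2_dfr(levels_pa, spec$levels_db, function(pa, dbl) {
        b <- simulate_recording(seg, tone_spec(f, pa),
                                n_reps = spec$n_reps, fs = spec$fs,
                                duration = spec$duration)
        if (keep == "bundles")
          bundles[[length(bundles) + 1L]] <<- b
        r <- extract_response(b, f, alpha = alpha)
        tibble::tibble(segment = s, freq = f, level_db = dbl, level_pa = pa,
                       magnitude = r$magnitude, phase = r$phase,
                       rayleigh_p = r$rayleigh_p, n_reps = r$n_reps,
                       passed = r$passed)
      })
      curves[[length(curves) + 1L]] <- rows
    }
  }
  structure(list(spec = spec, configs = configs,
                 curves = dplyr::bind_rows(curves), bundles = bundles),
            class = "hopf_cohort")
}

#' @export
print.hopf_cohort <- function(x, ...) {
  cat(sprintf("<hopf_cohort> %d segments, CFs %g-%g Hz, %d levels, EP %s\n",
              x$spec$n_segments, min(x$configs$cf), max(x$configs$cf),
              length(x$spec$levels_db), if (x$spec$ep_on) "on" else "off"))
  invisible(x)
}
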