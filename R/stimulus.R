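#' Sound-pressure level conversions
#'
#' Convert between pressure amplitude in pascal and dB SPL re 20 uPa.
#'
#' @param db,pa Levels in dB SPL / pressure amplitudes in Pa.
#' @return Numeric vector.
#' @examples
#' db_to_pa(94)  # ~1 Pa
#' pa_to_db(db_to_pa(60))
#' @export
db_to_pa <- function(db) 20e-6 * 10^(db / 20)

#' @rdname db_to_pa
#' @export
pa_to_db <- function(pa) {
  if (any(pa <= 0)) stop("pressure must be > 0 to express in dB", call. = FALSE)
  20 * log10(pa / 20e-6)
}

#' Tone specifications
#'
#' A tidy table of pure-tone components: frequency (Hz), pressure amplitude
#' (Pa) and starting phase (rad).
#'
#' @param freq Frequencies in Hz (> 0).
#' @param level Pressure amplitudes in Pa (>= 0). Use [db_to_pa()] for dB SPL.
#' @param phase Starting phases in rad (recycled).
#' @return A tibble with columns `freq`, `level`, `phase`.
#' @examples
#' tone_spec(freq = c(1230, 1236), level = db_to_pa(60))
#' @export
tone_spec <- function(freq, level, phase = 0) {
  stopifnot(is.numeric(freq), is.numeric(level))
  if (any(freq <= 0)) stop("`freq` must be > 0", call. = FALSE)
  if (any(level < 0)) stop("`level` must be >= 0", call. = FALSE)
  tibble::tibble(freq = freq,
                 level = rep_len(level, length(freq)),
                 phase = rep_len(phase, length(freq)))
}

# raised-cosine on/off envelope
taper_envelope <- function(n, fs, taper_ms) {
  env <- rep(1, n)
  n_ramp <- round(taper_ms / 1000 * fs)
  if (n_ramp > 0) {
    t <- seq_len(n_ramp) - 1
    ramp <- 0.5 * (1 - cos(pi * t / n_ramp))
    env[seq_len(n_ramp)] <- ramp
    env[n - seq_len(n_ramp) + 1L] <- ramp
  }
  env
}

#' Synthesize a tapered pure tone
#'
#' Generates `level * cos(2 pi freq t + phase)` with raised-cosine onset and
#' offset ramps.
#'
#' @param freq Frequency (Hz).
#' @param level Pressure amplitude (Pa).
#' @param phase Starting phase (rad).
#' @param duration Duration (s); must exceed `2 * taper_ms / 1000`.
#' @param fs Sampling rate (Hz); must exceed `4 * freq`.
#' @param taper_ms On/off ramp duration (ms); 0 disables tapering.
#' @param grid_lock If `TRUE`, require `freq * duration` to be an integer so
#'   the tone falls exactly on the FFT grid of the full window.
#' @return A `waveform`: list with `samples` (Pa), `fs`, `taper_ms`.
#' @examples
#' w <- make_tone(1000, level = 1, duration = 0.5, fs = 16000)
#' @export
make_tone <- function(freq, level, phase = 0, duration, fs, taper_ms = 10,
                      grid_lock = FALSE) {
  synthesize_tones(tone_spec(freq, level, phase), duration, fs, taper_ms,
                   grid_lock = grid_lock)
}

#' Synthesize a multitone waveform
#'
#' Sample-wise sum of the component tones of a [tone_spec()] (or the tones of
#' a [design_zwuis()] result), under a single shared raised-cosine taper.
#'
#' @param tones A tibble with columns `freq`, `level`, `phase`, or a
#'   `zwuis_design`.
#' @inheritParams make_tone
#' @param clip_warn Warn if the peak exceeds this pressure (Pa).
#' @return A `waveform` object.
#' @examples
#' w <- synthesize_tones(tone_spec(c(1000, 3000), 0.1), 0.5, 16000)
#' @export
synthesize_tones <- function(tones, duration, fs, taper_ms = 10,
                             grid_lock = FALSE, clip_warn = Inf) {
  if (inherits(tones, "zwuis_design")) tones <- tones$tones
  stopifnot(is.data.frame(tones))
  if (duration <= 2 * taper_ms / 1000)
    stop("`duration` must exceed twice the taper", call. = FALSE)
  if (nrow(tones) > 0 && fs <= 4 * max(tones$freq))
    stop("`fs` must exceed 4x the highest tone frequency", call. = FALSE)
  if (grid_lock && nrow(tones) > 0) {
    cyc <- tones$freq * duration
    if (any(abs(cyc - round(cyc)) > 1e-9))
      stop("tone frequencies are not on the FFT grid of the window ",
           "(freq * duration must be integer)", call. = FALSE)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (i in seq_len(nrow(tones)))
    x <- x + tones$level[i] * cos(2 * pi * tones$freq[i] * t + tones$phase[i])
  x <- x * taper_envelope(n, fs, taper_ms)
  if (max(abs(x)) > clip_warn)
    warning("waveform peak exceeds the clipping ceiling", call. = FALSE)
  structure(list(samples = x, fs = fs, taper_ms = taper_ms),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples at %g Hz, taper %g ms, peak %.3g Pa\n",
              length(x$samples), x$fs, x$taper_ms, max(abs(x$samples))))
  invisible(x)
}
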