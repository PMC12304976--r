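#' Rayleigh test for phase locking
#'
#' Tests a sample of circular phases against uniformity. The statistic is
#' `Z = n * Rbar^2` with mean resultant length `Rbar`; the p-value uses the
#' standard second-order correction
#' `p = exp(-Z) * (1 + (2Z - Z^2) / (4n))`, accurate at small-to-moderate
#' repetition counts, clamped to `[0, 1]`.
#'
#' @param phases Phase angles in rad.
#' @return A list with `n`, `r_bar`, `z`, `p_value`.
#' @examples
#' rayleigh_test(rep(0.3, 10))       # perfectly locked
#' rayleigh_test(c(0, 2, 4) * pi / 3) # balanced, p ~ 1
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2) stop("need at least 2 phases for a Rayleigh test", call. = FALSE)
  r_bar <- Mod(mean(exp(1i * phases)))
  z <- n * r_bar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  list(n = n, r_bar = r_bar, z = z, p_value = min(max(p, 0), 1))
}

# frequency -> FFT bin index (1-based), erroring off-grid
fft_bin <- function(freq, fs, n) {
  k <- freq * n / fs
  if (abs(k - round(k)) > 1e-6)
    stop("frequency ", freq, " Hz is not on the FFT grid of the ",
         "analysis window (no interpolation is performed)", call. = FALSE)
  as.integer(round(k))
}

#' Extract a phase-locked phasor response
#'
#' Computes the per-repetition complex phasor of a recording bundle at one
#' stimulus frequency (amplitude/phase in the cosine convention), coherently
#' averages the repetitions, and gates the result with a Rayleigh test on the
#' per-repetition phases. Responses whose phases are indistinguishable from
#' uniform are flagged as not phase locked.
#'
#' @param bundle A `recording_bundle` (see [simulate_recording()] or
#'   [read_bundle()]).
#' @param freq Analysis frequency (Hz); must lie on the FFT grid of the
#'   repetition window (an integer number of cycles).
#' @param alpha Rayleigh significance level; 0.001 is the microphonic
#'   criterion, 0.01 the vibrometry criterion.
#' @return One-row tibble: `freq`, `magnitude`, `phase`, `rayleigh_p`,
#'   `n_reps`, `passed`.
#' @export
extract_response <- function(bundle, freq, alpha = 0.001) {
  stopifnot(inherits(bundle, "recording_bundle"))
  reps <- bundle$reps
  if (nrow(reps) < 2)
    stop("need at least 2 repetitions to assess phase locking", call. = FALSE)
  n <- ncol(reps)
  k <- fft_bin(freq, bundle$fs, n)
  tt <- (seq_len(n) - 1) / bundle$fs
  basis <- exp(-2i * pi * freq * tt)
  phasors <- as.vector(reps %*% basis) * (2 / n)
  m <- mean(phasors)
  rt <- rayleigh_test(Arg(phasors))
  tibble::tibble(freq = freq, magnitude = Mod(m), phase = Arg(m),
                 rayleigh_p = rt$p_value, n_reps = nrow(reps),
                 passed = rt$p_value < alpha)
}

#' Coherently averaged magnitude spectrum
#'
#' Magnitude of the mean complex spectrum across repetitions. Because the
#' stimulus is phase locked to acquisition, coherent (complex) averaging
#' suppresses the noise floor by `sqrt(n_reps)` while leaving phase-locked
#' lines untouched.
#'
#' @param bundle A `recording_bundle`.
#' @return Tibble with `freq` (Hz, up to Nyquist) and `magnitude` (amplitude
#'   units, one-sided scaling).
#' @export
average_spectrum <- function(bundle) {
  stopifnot(inherits(bundle, "recording_bundle"))
  reps <- bundle$reps
  n <- ncol(reps)
  sp <- stats::mvfft(t(reps))            # columns = repetitions
  avg <- rowMeans(sp) * (2 / n)
  n_keep <- floor(n / 2) + 1L
  tibble::tibble(freq = (seq_len(n_keep) - 1) * bundle$fs / n,
                 magnitude = Mod(avg[seq_len(n_keep)]))
}

# odd-order distortion-product frequencies n*f1 - (n-1)*f2 (and mirrored)
dp_frequencies <- function(f1, f2, max_order = 3) {
  stopifnot(f1 < f2, 2 * f1 - f2 > 0)
  purrr::map_dfr(2:max_order, function(nn) {
    tibble::tibble(order = 2L * nn - 1L,   # 2f1-f2 is cubic (order 3)
                   freq = c(nn * f1 - (nn - 1) * f2, nn * f2 - (nn - 1) * f1),
                   side = c("low", "high"))
  })
}

#' Measure distortion products across a level series
#'
#' For each level of a two-tone series, extracts Rayleigh-gated phasors at
#' the primaries and at the odd-order combination tones
#' `n f1 - (n-1) f2` / `n f2 - (n-1) f1` (cubic, quintic, ...), and reports
#' the per-level ratio of the mean gate-passing cubic distortion-product
#' magnitude to the mean primary magnitude. For a system operating near a
#' Hopf bifurcation this ratio is nearly level independent, whereas for a
#' memoryless saturating nonlinearity it grows with level.
#'
#' @param bundles List of `recording_bundle`s, one per stimulus level (each
#'   driven by the same two primaries at a different level).
#' @param f1,f2 Primary frequencies (Hz), `f1 < f2`, with `2 f1 - f2 > 0`.
#' @param max_order Highest `n` in `n f1 - (n-1) f2` (default 3: cubic and
#'   quintic products).
#' @param alpha Rayleigh gate level.
#' @return A `dp_report`: list with `components` (tibble: one row per level x
#'   frequency with role, order, magnitude, gate) and `ratios` (tibble: one
#'   row per level with `ratio` = mean cubic DP / mean primary, `NA` when no
#'   cubic DP passes the gate).
#' @export
measure_dps <- function(bundles, f1, f2, max_order = 3, alpha = 0.001) {
  stopifnot(is.list(bundles), length(bundles) > 0)
  dps <- dp_frequencies(f1, f2, max_order)
  if (any(dps$freq %in% c(f1, f2)))
    stop("a distortion product collides with a primary; ",
         "choose different primaries", call. = FALSE)
  targets <- dplyr::bind_rows(
    tibble::tibble(role = "primary", order = 1L, freq = c(f1, f2),
                   side = c("low", "high")),
    dplyr::mutate(dps, role = "dp")
  )
  components <- purrr::imap_dfr(bundles, function(b, i) {
    lev <- b$level_pa
    purrr::pmap_dfr(targets, function(role, order, freq, side) {
      r <- extract_response(b, freq, alpha = alpha)
      tibble::tibble(level_index = as.integer(i),
                     level_pa = lev %||% NA_real_,
                     role = role, order = order, side = side,
                     freq = freq, magnitude = r$magnitude,
                     rayleigh_p = r$rayleigh_p, passed = r$passed)
    })
  })
  ratios <- components |>
    dplyr::group_by(.data$level_index, .data$level_pa) |>
    dplyr::summarise(
      primary_mean = mean(.data$magnitude[.data$role == "primary"]),
      dp_cubic_mean = mean(.data$magnitude[.data$role == "dp" &
                                             .data$order == 3L &
                                             .data$passed]),
      n_dp_passed = sum(.data$role == "dp" & .data$order == 3L & .data$passed),
      .groups = "drop") |>
    dplyr::mutate(ratio = ifelse(.data$n_dp_passed > 0,
                                 .data$dp_cubic_mean / .data$primary_mean,
                                 NA_real_))
  structure(list(components = components, ratios = ratios,
                 f1 = f1, f2 = f2, max_order = max_order, alpha = alpha),
            class = "dp_report")
}

#' @export
print.dp_report <- function(x, ...) {
  cat(sprintf("<dp_report> f1 = %g Hz, f2 = %g Hz, %d levels\n",
              x$f1, x$f2, nrow(x$ratios)))
  print(x$ratios)
  invisible(x)
}
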