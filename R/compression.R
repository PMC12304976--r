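# fast closed-form simple OLS of y on x: slope, intercept, slope SE
ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, se = se,
       rss = sum(res^2), n = n)
}

# gate-passing, positive-magnitude points of one curve, in level order
usable_points <- function(curve) {
  keep <- (is.na(curve$passed) | curve$passed) & curve$magnitude > 0
  dplyr::arrange(curve[keep, , drop = FALSE], .data$level_pa)
}

#' Local log-log compression slopes
#'
#' Slides windows of 3 and of 4 consecutive gate-passing points along each
#' response curve and fits ordinary least squares in doubly logarithmic
#' coordinates (`log10` pressure vs `log10` magnitude), yielding many
#' overlapping local slope estimates per curve. Estimates whose slope
#' standard error exceeds `se_cutoff` are marked as not retained; points
#' failing the Rayleigh gate are excluded before windowing.
#'
#' @param curve Response-curve tibble with columns `level_pa`, `magnitude`,
#'   and optionally `passed`, `segment`, `freq` (curves are processed per
#'   `segment` x `freq` group).
#' @param se_cutoff Retention threshold on the slope standard error
#'   (default 0.15).
#' @return Tibble of `slope_estimate` rows: grouping columns, `n_points`
#'   (3 or 4), `level_lo_db`/`level_hi_db` (window bounds, when `level_db`
#'   is present), `slope`, `se`, `retained`.
#' @examples
#' curve <- tibble::tibble(level_pa = 10^seq(-3, 0, 0.25),
#'                         magnitude = (10^seq(-3, 0, 0.25))^(1 / 3))
#' local_slopes(curve)
#' @export
local_slopes <- function(curve, se_cutoff = 0.15) {
  stopifnot(is.data.frame(curve), se_cutoff >= 0)
  g <- intersect(c("segment", "freq"), names(curve))
  groups <- if (length(g)) dplyr::group_split(dplyr::group_by(
    curve, dplyr::across(dplyr::all_of(g)))) else list(curve)
  out <- purrr::map_dfr(groups, function(cv) {
    pts <- usable_points(cv)
    m <- nrow(pts)
    if (m < 3) return(tibble::tibble())
    x <- log10(pts$level_pa)
    y <- log10(pts$magnitude)
    has_db <- "level_db" %in% names(pts)
    purrr::map_dfr(3:4, function(np) {
      if (m < np) return(tibble::tibble())
      purrr::map_dfr(seq_len(m - np + 1L), function(i) {
        idx <- i:(i + np - 1L)
        fit <- ols_slope(x[idx], y[idx])
        row <- tibble::tibble(
          n_points = np,
          level_lo_db = if (has_db) pts$level_db[idx[1]] else NA_real_,
          level_hi_db = if (has_db) pts$level_db[idx[np]] else NA_real_,
          slope = fit$slope, se = fit$se,
          retained = fit$se <= se_cutoff)
        for (col in rev(g)) row <- tibble::add_column(
          row, !!col := cv[[col]][1], .before = 1)
        row
      })
    })
  })
  if (nrow(out) == 0)
    stop("insufficient data: no curve has >= 3 gate-passing points",
         call. = FALSE)
  out
}

#' Per-segment minimum compressive slope
#'
#' Extracts, for each segment, the minimum retained local slope as an
#' objective measure of maximal compression. When a segment's protocol spans
#' several stimulus frequencies, the minimum is searched within a moving
#' frequency window (default 500 Hz wide, stepped by 10 Hz) and the global
#' per-segment minimum is reported together with its window center.
#'
#' @param estimates Output of [local_slopes()] (needs `slope`, `se`,
#'   `retained`, and optionally `segment`, `freq`).
#' @param freq_window Moving-window width along the frequency axis (Hz).
#' @param freq_step Window step (Hz).
#' @return Tibble with one row per segment: `segment`, `freq` (window center
#'   or the single stimulus frequency), `min_slope`, `se`, `n_retained`,
#'   `has_retained`. Segments with no retained estimate get `NA` slopes and
#'   `has_retained = FALSE`.
#' @export
min_slope <- function(estimates, freq_window = 500, freq_step = 10) {
  stopifnot(is.data.frame(estimates))
  if (!"segment" %in% names(estimates)) estimates$segment <- 1L
  if (!"freq" %in% names(estimates)) estimates$freq <- NA_real_
  purrr::map_dfr(split(estimates, estimates$segment), function(e) {
    ret <- e[e$retained, , drop = FALSE]
    if (nrow(ret) == 0)
      return(tibble::tibble(segment = e$segment[1], freq = NA_real_,
                            min_slope = NA_real_, se = NA_real_,
                            n_retained = 0L, has_retained = FALSE))
    freqs <- unique(ret$freq)
    if (length(freqs) > 1L && all(is.finite(freqs))) {
      centers <- seq(min(freqs), max(freqs), by = freq_step)
      best <- NULL
      for (ctr in centers) {
        inw <- ret[abs(ret$freq - ctr) <= freq_window / 2, , drop = FALSE]
        if (nrow(inw) == 0) next
        i <- which.min(inw$slope)
        if (is.null(best) || inw$slope[i] < best$min_slope)
          best <- tibble::tibble(freq = ctr, min_slope = inw$slope[i],
                                 se = inw$se[i])
      }
      tibble::tibble(segment = e$segment[1], freq = best$freq,
                     min_slope = best$min_slope, se = best$se,
                     n_retained = nrow(ret), has_retained = TRUE)
    } else {
      i <- which.min(ret$slope)
      tibble::tibble(segment = e$segment[1], freq = ret$freq[i],
                     min_slope = ret$slope[i], se = ret$se[i],
                     n_retained = nrow(ret), has_retained = TRUE)
    }
  })
}

#' Cohort trend of minimum slopes
#'
#' Fits the per-segment minimum compressive slopes against stimulus
#' frequency by ordinary least squares (`min_slope ~ freq`), reporting the
#' trend line `y = m x + q` with 95% confidence intervals, and the mean of
#' the minima with its standard error and 95% CI. A trend slope `m`
#' indistinguishable from zero with minima clustering near 1/3 is the
#' cohort-level signature of a critical power law; saturating or passive
#' nulls scatter without a consistent lower bound.
#'
#' @param minima Output of [min_slope()]; needs >= 3 segments with retained
#'   minima and nondegenerate frequency spread.
#' @return An object of class `cohort_trend` with components `model` (the
#'   `lm` fit), `minima`, `m`, `q`, `ci95_m`, `ci95_q`, `mean_min`,
#'   `se_mean`, `ci95_mean`, `n`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
cohort_trend <- function(minima) {
  stopifnot(is.data.frame(minima))
  ok <- minima[minima$has_retained & is.finite(minima$min_slope) &
                 is.finite(minima$freq), , drop = FALSE]
  if (nrow(ok) < 3) stop("need >= 3 segments with retained minima",
                         call. = FALSE)
  if (length(unique(ok$freq)) < 2)
    stop("degenerate frequency spread: trend is not identifiable",
         call. = FALSE)
  fit <- stats::lm(min_slope ~ freq, data = ok)
  ci <- stats::confint(fit, level = 0.95)
  mm <- mean(ok$min_slope)
  se <- stats::sd(ok$min_slope) / sqrt(nrow(ok))
  tq <- stats::qt(0.975, nrow(ok) - 1)
  structure(
    list(model = fit, minima = ok,
         m = unname(stats::coef(fit)["freq"]),
         q = unname(stats::coef(fit)["(Intercept)"]),
         ci95_m = unname(ci["freq", ]),
         ci95_q = unname(ci["(Intercept)", ]),
         mean_min = mm, se_mean = se,
         ci95_mean = c(mm - tq * se, mm + tq * se),
         n = nrow(ok)),
    class = "cohort_trend"
  )
}

#' @export
print.cohort_trend <- function(x, ...) {
  cat("<cohort_trend>\n")
  cat(sprintf("  n segments: %d\n", x$n))
  cat(sprintf("  trend: y = m x + q, m = %.3g [%.3g, %.3g] /Hz, q = %.3f [%.3f, %.3f]\n",
              x$m, x$ci95_m[1], x$ci95_m[2], x$q, x$ci95_q[1], x$ci95_q[2]))
  cat(sprintf("  mean minimum slope: %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_min, x$se_mean, x$ci95_mean[1], x$ci95_mean[2]))
  invisible(x)
}

#' Convert a response curve to a sensitivity curve
#'
#' Replaces magnitudes by sensitivity `S = magnitude / pressure`. On log-log
#' axes the slope of `S` is the response slope minus one: the critical
#' cube-root law maps to a -2/3 sensitivity decline and linear growth maps
#' to a level-independent sensitivity.
#'
#' @param curve Response-curve tibble with `level_pa` (> 0) and `magnitude`.
#' @return The curve with `magnitude` replaced by sensitivity and the
#'   original magnitude preserved in `raw_magnitude`.
#' @export
sensitivity_curve <- function(curve) {
  stopifnot(is.data.frame(curve))
  if (any(curve$level_pa <= 0))
    stop("sensitivity requires strictly positive pressures", call. = FALSE)
  curve$raw_magnitude <- curve$magnitude
  curve$magnitude <- curve$magnitude / curve$level_pa
  curve
}

# least-squares of the hinge model y = s_infl + s1 * min(x - bp, 0)
hinge_fit <- function(x, y, bp) {
  u <- pmin(x - bp, 0)
  if (all(u == 0) || all(u == u[1])) return(NULL)
  fit <- ols_slope(u, y)
  list(s1 = fit$slope, s_infl = fit$intercept, rss = fit$rss)
}

#' Piecewise-linear fit of a sensitivity curve
#'
#' Fits, in doubly logarithmic coordinates, the continuous two-segment model
#' used to locate the inflection point of a sensitivity curve: a first
#' segment of negative slope joined at a breakpoint `(p_infl, s_infl)` to a
#' flat segment. The breakpoint is searched on a grid of candidate positions
#' at and between the observed levels and the global least-squares minimizer
#' with negative first-segment slope is returned; when no breakpoint yields
#' a negative slope the curve is flagged as showing no compression.
#'
#' @param sens Sensitivity curve ([sensitivity_curve()] output) with >= 5
#'   gate-passing points.
#' @return An object of class `piecewise_fit`: `s1` (first-segment slope),
#'   `p_infl` (log10 Pa), `s_infl` (log10 sensitivity), `rss`, `n`,
#'   `compressive` (FALSE when flagged), `data` (the fitted points).
#' @export
piecewise_fit <- function(sens) {
  stopifnot(is.data.frame(sens))
  pts <- usable_points(sens)
  if (nrow(pts) < 5)
    stop("piecewise fit needs >= 5 gate-passing points", call. = FALSE)
  x <- log10(pts$level_pa)
  y <- log10(pts$magnitude)
  xs <- sort(unique(x))
  cand <- sort(unique(c(xs, (xs[-1] + xs[-length(xs)]) / 2)))
  cand <- cand[cand > min(x) & cand <= max(x)]
  best <- NULL
  for (bp in cand) {
    f <- hinge_fit(x, y, bp)
    if (is.null(f) || f$s1 >= 0) next
    if (is.null(best) || f$rss < best$rss)
      best <- c(f, list(p_infl = bp))
  }
  if (is.null(best))
    return(structure(list(s1 = NA_real_, p_infl = NA_real_,
                          s_infl = NA_real_, rss = NA_real_,
                          n = nrow(pts), compressive = FALSE, data = pts),
                     class = "piecewise_fit"))
  structure(list(s1 = best$s1, p_infl = best$p_infl, s_infl = best$s_infl,
                 rss = best$rss, n = nrow(pts), compressive = TRUE,
                 data = pts),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (!x$compressive) {
    cat("<piecewise_fit> no compression detected (curve treated as linear)\n")
  } else {
    cat(sprintf(
      "<piecewise_fit> s1 = %.3f, inflection at log10 P = %.3f, log10 S = %.3f (rss %.3g, n %d)\n",
      x$s1, x$p_infl, x$s_infl, x$rss, x$n))
  }
  invisible(x)
}

#' Align sensitivity curves at their inflection points and average
#'
#' Fits each segment's sensitivity curve with [piecewise_fit()], translates
#' every curve in log-log space so its inflection point moves to the origin,
#' pools the points, applies a running average along the pressure axis, and
#' estimates local slopes of the averaged curve in four-point sliding
#' windows with 95% confidence half-widths from the t distribution with
#' `n - 2 = 2` degrees of freedom.
#'
#' @param sens Sensitivity tibble covering several segments (`segment`
#'   column) with `level_pa`, `magnitude`, `passed`.
#' @param bin_width Running-average bin width in log10-pressure units.
#' @return List of class `aligned_sensitivity`: `average` (tibble: `x` bin
#'   center, `mean_log_s`, `sd_log_s`, `n`), `window_slopes` (tibble: `x`,
#'   `slope`, `ci_half`), `n_curves` (number aligned), `fits` (per-segment
#'   piecewise fits).
#' @export
align_and_average <- function(sens, bin_width = 0.1) {
  stopifnot(is.data.frame(sens), "segment" %in% names(sens))
  pieces <- split(sens, sens$segment)
  fits <- list(); shifted <- list()
  for (nm in names(pieces)) {
    f <- tryCatch(piecewise_fit(pieces[[nm]]), error = function(e) NULL)
    if (is.null(f) || !f$compressive) next
    fits[[nm]] <- f
    pts <- f$data
    shifted[[nm]] <- tibble::tibble(
      segment = pieces[[nm]]$segment[1],
      x = log10(pts$level_pa) - f$p_infl,
      y = log10(pts$magnitude) - f$s_infl)
  }
  if (length(shifted) < 2)
    stop("need >= 2 curves with successful piecewise fits", call. = FALSE)
  pool <- dplyr::bind_rows(shifted)
  bins <- round(pool$x / bin_width)
  average <- pool |>
    dplyr::mutate(bin = bins) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(x = mean(.data$x), mean_log_s = mean(.data$y),
                     sd_log_s = stats::sd(.data$y), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$x) |>
    dplyr::select(-"bin")
  if (nrow(average) < 4)
    stop("insufficient data: fewer than 4 averaged points", call. = FALSE)
  tcrit <- stats::qt(0.975, df = 2)
  window_slopes <- purrr::map_dfr(seq_len(nrow(average) - 3L), function(i) {
    idx <- i:(i + 3L)
    fit <- ols_slope(average$x[idx], average$mean_log_s[idx])
    tibble::tibble(x = mean(average$x[idx]), slope = fit$slope,
                   ci_half = tcrit * fit$se)
  })
  structure(list(average = average, window_slopes = window_slopes,
                 n_curves = length(shifted), fits = fits),
            class = "aligned_sensitivity")
}

#' @export
print.aligned_sensitivity <- function(x, ...) {
  cat(sprintf("<aligned_sensitivity> %d curves aligned, %d averaged points\n",
              x$n_curves, nrow(x$average)))
  invisible(x)
}

#' Classify a segment as nonlinear
#'
#' A segment counts as nonlinear (compressive) when any retained local slope
#' is smaller than 0.5.
#'
#' @param estimates Output of [local_slopes()].
#' @param threshold Classification threshold (default 0.5, strict `<`).
#' @return Logical scalar.
#' @export
classify_nonlinear <- function(estimates, threshold = 0.5) {
  stopifnot(is.data.frame(estimates))
  ret <- estimates[estimates$retained, , drop = FALSE]
  if (nrow(ret) == 0)
    stop("no retained slope estimates to classify", call. = FALSE)
  any(ret$slope < threshold)
}

#' Detect a run of sublinear growth
#'
#' Flags a response curve that shows at least three consecutive
#' point-to-point log-log increments with slope below a threshold — the
#' per-series sublinearity criterion used to map compressive regions.
#'
#' @param curve Response-curve tibble (`level_pa`, `magnitude`, optional
#'   `passed`) with >= 4 gate-passing points.
#' @param slope_threshold Sublinearity threshold on point-to-point slopes
#'   (default 0.9, i.e. one minus a 0.1 linearity margin).
#' @return Logical scalar: `TRUE` when some run of >= 3 consecutive
#'   increments is sublinear.
#' @export
sublinear_run_mask <- function(curve, slope_threshold = 0.9) {
  stopifnot(is.data.frame(curve))
  pts <- usable_points(curve)
  if (nrow(pts) < 4)
    stop("need >= 4 gate-passing points", call. = FALSE)
  inc <- diff(log10(pts$magnitude)) / diff(log10(pts$level_pa))
  r <- rle(inc < slope_threshold)
  any(r$lengths[r$values] >= 3)
}
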