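#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort trend fit
#'
#' @param x A [cohort_trend()] object.
#' @param ... Unused.
#' @return One row per coefficient of the trend line `y = m x + q`:
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.cohort_trend <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("q (intercept)", "m (per Hz)"),
    estimate = c(x$q, x$m),
    std.error = s[, "Std. Error"],
    conf.low = c(x$ci95_q[1], x$ci95_m[1]),
    conf.high = c(x$ci95_q[2], x$ci95_m[2]))
}

#' @rdname tidy.cohort_trend
#' @export
glance.cohort_trend <- function(x, ...) {
  tibble::tibble(n_segments = x$n, mean_min_slope = x$mean_min,
                 se_mean = x$se_mean,
                 ci95_lo = x$ci95_mean[1], ci95_hi = x$ci95_mean[2],
                 r.squared = summary(x$model)$r.squared)
}

#' Tidy a piecewise sensitivity fit
#'
#' @param x A [piecewise_fit()] object.
#' @param ... Unused.
#' @return One-row tibble with `s1`, `p_infl`, `s_infl`, `rss`, `n`,
#'   `compressive`.
#' @export
tidy.piecewise_fit <- function(x, ...) {
  tibble::tibble(s1 = x$s1, p_infl = x$p_infl, s_infl = x$s_infl,
                 rss = x$rss, n = x$n, compressive = x$compressive)
}

#' @rdname tidy.piecewise_fit
#' @export
glance.piecewise_fit <- function(x, ...) tidy.piecewise_fit(x)
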