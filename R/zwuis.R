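# All combination-tone values (as integer grid indices) that a set of
# primaries can generate with total coefficient weight 2..order.  Works on
# the delta_f index grid so the collision test is exact integer arithmetic.
zwuis_combination_indices <- function(indices, order = 3) {
  stopifnot(order %in% c(2L, 3L))
  k <- length(indices)
  out <- integer(0)
  # weight 2: 2 f_i; f_i +/- f_j
  out <- c(out, 2L * indices)
  if (k >= 2) {
    pr <- utils::combn(indices, 2L)
    out <- c(out, pr[1, ] + pr[2, ], abs(pr[1, ] - pr[2, ]))
  }
  if (order >= 3L) {
    # weight 3: 3 f_i; 2 f_i +/- f_j; |2 f_i - f_j| both orderings;
    # f_i +/- f_j +/- f_k over distinct triples
    out <- c(out, 3L * indices)
    if (k >= 2) {
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i == j) next
        out <- c(out, 2L * indices[i] + indices[j],
                 abs(2L * indices[i] - indices[j]))
      }
    }
    if (k >= 3) {
      tr <- utils::combn(indices, 3L)
      for (s2 in c(-1L, 1L)) for (s3 in c(-1L, 1L))
        out <- c(out, abs(tr[1, ] + s2 * tr[2, ] + s3 * tr[3, ]))
    }
  }
  unique(out)
}

# TRUE when some order-<=`order` combination tone lands on a primary
zwuis_has_collision <- function(indices, order = 3) {
  any(zwuis_combination_indices(indices, order) %in% indices)
}

#' Design a zwuis multitone stimulus
#'
#' Draws `K` distinct tone frequencies on a `delta_f` grid such that no
#' low-order combination tone (sums, differences and harmonics with total
#' coefficient weight up to `order`) coincides with any primary. This
#' guarantees that distortion products generated by the system under test
#' never contaminate the response measured at a primary frequency, so a
#' single multitone presentation can characterize several frequencies
#' simultaneously. Designs are found by seeded rejection sampling and are
#' deterministic given `seed`.
#'
#' @param K Number of tones (>= 2).
#' @param f_min,f_max Frequency range (Hz), `f_max > f_min >= delta_f`.
#' @param delta_f Frequency grid resolution (Hz); with 1/`delta_f`-second
#'   analysis windows all primaries and their combination tones fall on FFT
#'   bins.
#' @param order Maximum combination order checked (2 or 3).
#' @param seed Integer seed (frequencies and phases are reproducible).
#' @param max_tries Rejection-sampling budget.
#' @return A `zwuis_design`: list with `delta_f`, `indices`, `order_checked`,
#'   and `tones` (a [tone_spec()] tibble with uniform random phases and unit
#'   level, to be rescaled by the caller).
#' @examples
#' design_zwuis(K = 5, f_min = 500, f_max = 3000, delta_f = 10, seed = 1)
#' @export
design_zwuis <- function(K, f_min, f_max, delta_f, order = 3, seed = 1,
                         max_tries = 5000) {
  stopifnot(K >= 2, order %in% c(2L, 3L))
  if (!(f_max > f_min && f_min >= delta_f))
    stop("need f_max > f_min >= delta_f", call. = FALSE)
  i_min <- ceiling(f_min / delta_f)
  i_max <- floor(f_max / delta_f)
  if (i_max - i_min + 1L < K)
    stop("frequency grid too coarse for K tones", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    idx <- sort(sample(seq.int(i_min, i_max), K))
    if (!zwuis_has_collision(idx, order)) {
      phases <- stats::runif(K, 0, 2 * pi)
      return(structure(
        list(delta_f = delta_f, indices = idx, order_checked = as.integer(order),
             tones = tone_spec(freq = idx * delta_f, level = 1, phase = phases)),
        class = "zwuis_design"
      ))
    }
  }
  stop("no collision-free zwuis design found in ", max_tries,
       " tries; widen the band or reduce K (order-", order,
       " combination tones are the binding constraint)", call. = FALSE)
}

#' @export
print.zwuis_design <- function(x, ...) {
  cat(sprintf("<zwuis_design> %d tones on a %g Hz grid, order <= %d checked\n",
              length(x$indices), x$delta_f, x$order_checked))
  cat("  freqs:", paste(x$indices * x$delta_f, collapse = ", "), "Hz\n")
  invisible(x)
}
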