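# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: matrix normal equations instead of closed-form
# OLS, dense grid search instead of bracketed root finding, explicit loops
# instead of vectorized collision checks.

# OLS via normal equations: slope, intercept, slope SE, RSS
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  coefs <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  n <- length(x)
  sigma2 <- rss / (n - 2)
  covb <- sigma2 * solve(t(X) %*% X)
  list(intercept = coefs[1], slope = coefs[2],
       se = sqrt(covb[2, 2]), rss = rss)
}

# steady-state amplitude by dense grid search + local refinement
oracle_steady_amplitude <- function(epsilon, beta_re, beta_im, d_omega, F0) {
  lhs <- function(A) sqrt((beta_re * A^3 - epsilon * A)^2 +
                            (A * d_omega + beta_im * A^3)^2)
  upper <- max((F0 / beta_re)^(1 / 3) * 4, 1)
  grid <- seq(0, upper, by = 1e-6 * upper)
  i <- which.min(abs(lhs(grid) - F0))
  # refine once around the best grid point
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  fine <- seq(lo, hi, length.out = 4001)
  fine[which.min(abs(lhs(fine) - F0))]
}

# exhaustive order-<=3 combination-tone check, written as plain loops
oracle_zwuis_ok <- function(idx, order = 3) {
  k <- length(idx)
  primaries <- idx
  combos <- integer(0)
  for (a in -order:order) for (b in -order:order) for (cc in -order:order) {
    w <- abs(a) + abs(b) + abs(cc)
    if (w < 2 || w > order) next
    for (i in 1:k) for (j in 1:k) for (l in 1:k) {
      # coefficients attach to distinct primaries (unused slots need 0 coef)
      if ((a != 0 && b != 0 && i == j) ||
          (a != 0 && cc != 0 && i == l) ||
          (b != 0 && cc != 0 && j == l)) next
      v <- abs(a * idx[i] + b * idx[j] + cc * idx[l])
      combos <- c(combos, v)
    }
  }
  !any(unique(combos) %in% primaries)
}

# ideal response curve following a pure power law A = c * P^s
power_law_curve <- function(levels_db, s, c = 1, segment = 1L, freq = 1000) {
  pa <- db_to_pa(levels_db)
  tibble::tibble(segment = segment, freq = freq, level_db = levels_db,
                 level_pa = pa, magnitude = c * pa^s,
                 rayleigh_p = 0, n_reps = 20L, passed = TRUE)
}

# noise-only bundle built through the simulator (no stimulus energy at freq)
noise_bundle <- function(seed, n_reps = 10, fs = 4000, duration = 0.064) {
  seg <- segment_config(cf = 1000, epsilon = -1, ep_on = FALSE,
                        passive_gain = 0, noise_rms = 1, seed = seed)
  suppressWarnings(
    simulate_recording(seg, tone_spec(1000, 0.01), n_reps = n_reps,
                       fs = fs, duration = duration))
}

# brute-force piecewise (hinge) search over the same candidate definition:
# breakpoints at observed log-levels and their midpoints, solved by lm()
oracle_hinge_rss <- function(x, y) {
  xs <- sort(unique(x))
  cand <- sort(unique(c(xs, (xs[-1] + xs[-length(xs)]) / 2)))
  cand <- cand[cand > min(x) & cand <= max(x)]
  best <- Inf
  for (bp in cand) {
    u <- pmin(x - bp, 0)
    if (length(unique(u)) < 2) next
    fit <- stats::lm(y ~ u)
    if (coef(fit)[["u"]] >= 0) next
    rss <- sum(resid(fit)^2)
    if (rss < best) best <- rss
  }
  best
}
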