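# canonical response-curve columns, in write order
curve_columns <- c("segment", "freq", "level_db", "level_pa", "magnitude",
                   "phase", "rayleigh_p", "n_reps", "passed")

#' Read and write response curves
#'
#' Response curves are stored as plain UTF-8 CSV (comma separator, header
#' row, `.` decimal) with one row per frequency x level and columns
#' `segment, freq, level_db, level_pa, magnitude, phase, rayleigh_p, n_reps,
#' passed` (missing optional columns are tolerated). A legacy dialect
#' without the Rayleigh columns is accepted on read, with the gate marked as
#' not evaluated (`passed = NA`). Levels must be strictly increasing within
#' each curve. Numeric values round-trip exactly (17 significant digits).
#'
#' @param curve Response-curve tibble.
#' @param path File path.
#' @return `write_curve()` returns `path` invisibly; `read_curve()` returns
#'   a validated tibble.
#' @export
write_curve <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  cols <- intersect(curve_columns, names(curve))
  df <- as.data.frame(curve[, cols, drop = FALSE])
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("freq", "level_pa", "magnitude")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("curve file lacks required column(s): ",
         paste(missing, collapse = ", "), " (schema v1)", call. = FALSE)
  if (!"rayleigh_p" %in% names(df)) {
    df$rayleigh_p <- NA_real_
    df$passed <- NA            # legacy dialect: gate not evaluated
  }
  if (!"passed" %in% names(df)) df$passed <- NA
  df$passed <- as.logical(df$passed)
  out <- tibble::as_tibble(df)
  grp <- if ("segment" %in% names(out)) out$segment else rep(1L, nrow(out))
  for (g in split(seq_len(nrow(out)), list(grp, out$freq), drop = TRUE)) {
    if (is.unsorted(out$level_pa[g], strictly = TRUE))
      stop("curve levels must be strictly increasing within each curve",
           call. = FALSE)
  }
  out
}

#' Read and write recording bundles
#'
#' A recording bundle is stored as a pair of text files: `<path>.json` with
#' the metadata (sample rate, duration, repetition count, stimulus table,
#' segment snapshot, seed; schema v1) and `<path>.csv` with the repetition
#' matrix, one row per repetition, full 17-digit precision so arrays
#' round-trip exactly.
#'
#' @param bundle A `recording_bundle`.
#' @param path Base path (without extension).
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()`
#'   returns a `recording_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "recording_bundle"))
  meta <- list(
    schema = "recording_bundle/v1",
    fs = bundle$fs, duration = bundle$duration, n_reps = bundle$n_reps,
    n_samples = ncol(bundle$reps),
    level_pa = bundle$level_pa, level_db = bundle$level_db,
    seed = bundle$seed,
    stimulus = as.data.frame(bundle$stimulus),
    segment = if (!is.null(bundle$segment)) unclass(bundle$segment))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  m <- format(bundle$reps, digits = 17, scientific = TRUE, trim = TRUE)
  utils::write.table(m, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing bundle metadata file: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, "recording_bundle/v1"))
    stop("unsupported bundle schema: ",
         meta$schema %||% "<missing>", " (expected recording_bundle/v1)",
         call. = FALSE)
  reps <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(reps) <- NULL
  if (nrow(reps) != meta$n_reps || ncol(reps) != meta$n_samples)
    stop("bundle array shape does not match its metadata", call. = FALSE)
  segment <- NULL
  if (!is.null(meta$segment)) {
    s <- meta$segment
    segment <- segment_config(cf = s$cf, epsilon = s$epsilon,
                              beta_re = s$beta_re, beta_im = s$beta_im,
                              coupling = s$coupling,
                              passive_gain = s$passive_gain,
                              passive_phase = s$passive_phase,
                              obs_gain = s$obs_gain, noise_rms = s$noise_rms,
                              ep_on = s$ep_on, osc_noise = s$osc_noise,
                              seed = s$seed)
  }
  structure(
    list(reps = reps, fs = meta$fs, duration = meta$duration,
         n_reps = meta$n_reps,
         stimulus = tibble::as_tibble(meta$stimulus),
         segment = segment, seed = meta$seed,
         level_pa = meta$level_pa, level_db = meta$level_db),
    class = "recording_bundle"
  )
}
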