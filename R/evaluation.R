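# Validation harness: inject artifacts into synthetic recordings, apply
# correction methods, and quantify the error each method introduces into the
# eight HRV measures, averaged over seeded repetitions.

measure_names <- c("rmssd", "sdnn", "sdsd", "tp", "lf", "hf", "sd1", "sd2")

#' Relative errors between two measure sets
#'
#' Per measure, `100 * |corrected - original| / original`; measures whose
#' original value is numerically zero (below `eps`) are excluded from the
#' mean rather than producing infinities, and the exclusion is recorded.
#'
#' @param original,corrected named numeric vectors as returned by
#'   [all_measures()].
#' @param eps magnitude below which an original measure counts as zero.
#' @return a list with `per_measure_pct` (named, `NA` for excluded
#'   measures), `mean_error_pct` (mean over included measures) and
#'   `excluded` (names of excluded measures).
#' @export
relative_errors <- function(original, corrected, eps = 1e-9) {
  nm <- names(original)
  if (is.null(nm) || !identical(nm, names(corrected))) {
    stop("original and corrected must share measure names")
  }
  excl <- abs(original) < eps
  if (all(excl)) stop("all measures excluded: original values are all zero")
  per <- rep(NA_real_, length(original))
  names(per) <- nm
  per[!excl] <- 100 * abs(corrected[!excl] - original[!excl]) / original[!excl]
  list(per_measure_pct = per,
       mean_error_pct = mean(per[!excl]),
       excluded = nm[excl])
}

parse_spec_string <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  list(name = parts[1],
       param = if (length(parts) > 1) as.numeric(parts[2]) else NULL)
}

method_compatible <- function(method, artifact_type) {
  peak_methods <- c("algorithm1", "median", "threshold", "identity")
  gap_methods <- c("algorithm2", "spline", "identity")
  method %in% switch(artifact_type, peak = peak_methods, gap = gap_methods)
}

apply_method <- function(m, contaminated, hr, original, ...) {
  switch(m$name,
    identity = original,
    algorithm1 = correct_peaks(contaminated, ...)$series,
    algorithm2 = fill_gaps(contaminated, hr)$series,
    median = median_filter(contaminated, width = m$param %||% 3),
    threshold = threshold_cubic(contaminated, threshold = m$param %||% 5),
    spline = cubic_spline_fill(contaminated),
    stop("unknown method: ", m$name))
}

#' Run an artifact-injection evaluation experiment
#'
#' For each repetition `r`, the seed `base_seed + r` drives one generator
#' stream used in fixed order by signal generation, artifact injection and
#' any stochastic correction. A synthetic RR/HR pair is generated from
#' `profile`, the eight measures are computed on the uncontaminated series,
#' one artifact is injected at a random interior position, every requested
#' method is applied, and the per-measure relative errors against the
#' uncontaminated measures are recorded. Errors are averaged over
#' repetitions first, then over measures.
#'
#' @param profile an [hrv_profile()].
#' @param artifact artifact descriptor: `"peak:2"`, `"peak:3"`, `"gap:3"`,
#'   `"gap:5"` or `"gap:7"`.
#' @param methods character vector of method descriptors: `"algorithm1"`,
#'   `"algorithm2"`, `"median:<width>"`, `"threshold:<t>"`, `"spline"`,
#'   `"identity"`. Peak artifacts pair with algorithm1/median/threshold,
#'   gaps with algorithm2/spline; `identity` (measures of the untouched
#'   original) is always allowed.
#' @param reps number of seeded repetitions.
#' @param base_seed base seed; repetition `r` uses `base_seed + r`.
#' @param ... passed to [correct_peaks()] for method `algorithm1`.
#' @return a list of `error_report` objects, one per method, each with
#'   `method`, `artifact`, `reps`, `per_measure_pct` (mean over reps),
#'   `mean_error_pct`, and `per_measure_sd` (across-repetition SD of the
#'   corrected measure values).
#' @export
run_experiment <- function(profile, artifact, methods, reps = 50,
                           base_seed = 1000, ...) {
  art <- parse_spec_string(artifact)
  if (!art$name %in% c("peak", "gap") || is.null(art$param)) {
    stop("artifact must be 'peak:<multiple>' or 'gap:<width>'")
  }
  parsed <- lapply(methods, parse_spec_string)
  for (m in parsed) {
    if (!method_compatible(m$name, art$name)) {
      stop("method '", m$name, "' is incompatible with artifact '",
           art$name, "'")
    }
  }
  nmeth <- length(parsed)
  err <- array(NA_real_, c(reps, length(measure_names), nmeth),
               dimnames = list(NULL, measure_names, methods))
  corr <- err
  for (r in seq_len(reps)) {
    with_seed(base_seed + r, {
      pair <- generate_rr_hr(profile)
      m0 <- all_measures(pair$rr)
      inj <- if (art$name == "peak") {
        inject_peak(pair$rr, multiple = art$param)
      } else {
        inject_gap(pair$rr, width = art$param)
      }
      for (k in seq_len(nmeth)) {
        series_c <- apply_method(parsed[[k]], inj$series, pair$hr, pair$rr, ...)
        mc <- all_measures(series_c)
        rel <- relative_errors(m0, mc)
        err[r, , k] <- rel$per_measure_pct
        corr[r, , k] <- mc
      }
    })
  }
  lapply(seq_len(nmeth), function(k) {
    errk <- matrix(err[, , k], nrow = reps,
                   dimnames = list(NULL, measure_names))
    corrk <- matrix(corr[, , k], nrow = reps,
                    dimnames = list(NULL, measure_names))
    per <- colMeans(errk, na.rm = TRUE)
    per[is.nan(per)] <- NA_real_
    structure(list(method = methods[k], artifact = artifact, reps = reps,
                   per_measure_pct = per,
                   mean_error_pct = mean(per, na.rm = TRUE),
                   per_measure_sd = apply(corrk, 2, sd)),
              class = "error_report")
  })
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %s on %s over %d reps: mean error %.2f%%\n",
              x$method, x$artifact, x$reps, x$mean_error_pct))
  print(round(x$per_measure_pct, 3))
  invisible(x)
}

#' Format evaluation reports as a table
#'
#' Renders a list of `error_report`s (from [run_experiment()]) either as an
#' aligned text table — method rows, one column per measure, mean error
#' last, with an `(sd)` sub-row of across-repetition SDs under stochastic
#' methods — or as a data frame suitable for CSV export.
#'
#' @param reports a non-empty list of `error_report` objects.
#' @param format `"text"` for display lines or `"df"` for a data frame.
#' @param digits decimal places in the text rendering.
#' @return a character vector of lines, or a data frame.
#' @export
format_report <- function(reports, format = c("text", "df"), digits = 2) {
  format <- match.arg(format)
  if (length(reports) == 0) stop("no reports to format")
  if (inherits(reports, "error_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    row <- as.data.frame(as.list(r$per_measure_pct))
    cbind(data.frame(artifact = r$artifact, method = r$method), row,
          data.frame(mean_error = r$mean_error_pct))
  }))
  if (format == "df") return(df)
  stochastic <- c("algorithm1", "algorithm2")
  num <- function(v) formatC(v, digits = digits, format = "f")
  header <- c("artifact", "method", measure_names, "mean_error")
  rows <- list(header)
  for (r in reports) {
    rows[[length(rows) + 1]] <-
      c(r$artifact, r$method, num(r$per_measure_pct), num(r$mean_error_pct))
    if (parse_spec_string(r$method)$name %in% stochastic) {
      rows[[length(rows) + 1]] <-
        c("", "(sd)", num(r$per_measure_sd), "")
    }
  }
  mat <- do.call(rbind, rows)
  widths <- apply(nchar(mat), 2, max)
  apply(mat, 1, function(r) {
    paste(mapply(function(s, w) formatC(s, width = w, flag = "-"), r, widths),
          collapse = "  ")
  })
}
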