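# Polysome-profile quantification: valley-anchored normalization of
# sucrose-gradient OD260 traces and the polysome/monosome ratio.
#
# The procedure: find the local minimum between the 60S subunit peak and the
# dominant 80S monosome peak and define it as X = 0; min-max normalize Y so
# the sample's minimum maps to 0 and maximum to 1; rescale X so the last
# datapoint maps to 100; the monosome fraction is the sum of normalized Y
# from X = 0 to the monosome/disome valley, the polysome fraction the sum
# from that valley to X = 100, and their ratio is the readout.

#' Construct a polysome trace
#'
#' @param x strictly increasing gradient positions (arbitrary units).
#' @param y OD260 readings, same length as `x` (>= 50 points).
#' @param meta optional list of metadata (sample id, condition, ...).
#' @return an object of class `polysome_trace`.
#' @export
polysome_trace <- function(x, y, meta = list()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_nq("parse_error", "x and y must have the same length")
  if (length(x) < 50)
    stop_nq("parse_error", "a trace needs at least 50 samples")
  if (any(diff(x) <= 0))
    stop_nq("non_monotonic_x", "x must be strictly increasing")
  dx <- diff(x)
  uniform <- (max(dx) - min(dx)) <= 0.01 * stats::median(dx)
  structure(list(x = x, y = y, meta = meta, uniform_spacing = uniform),
            class = "polysome_trace")
}

#' @export
print.polysome_trace <- function(x, ...) {
  cat(sprintf("<polysome_trace> %d samples, x in [%.3g, %.3g]%s\n",
              length(x$x), min(x$x), max(x$x),
              if (x$uniform_spacing) "" else " (non-uniform spacing)"))
  invisible(x)
}

#' Read a gradient trace from a two-column delimited file
#'
#' Accepts tab-, comma-, semicolon- or whitespace-delimited text with an
#' optional header line. Non-uniform x spacing triggers a warning unless
#' `resample = TRUE`, which linearly interpolates onto a uniform grid of
#' the same length (sum-based integration requires uniform spacing).
#'
#' @param path file path.
#' @param dialect `"auto"` or one of `"tab"`, `"comma"`, `"semicolon"`,
#'   `"whitespace"`.
#' @param resample interpolate non-uniform traces onto a uniform grid.
#' @param meta optional metadata list.
#' @return a [polysome_trace].
#' @export
load_trace <- function(path, dialect = "auto", resample = FALSE, meta = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_nq("parse_error", sprintf("'%s' is empty", path))
  sep <- switch(dialect, tab = "\t", comma = ",", semicolon = ";",
                whitespace = "", auto = {
                  probe <- lines[[min(2, length(lines))]]
                  if (grepl("\t", probe)) "\t"
                  else if (grepl(",", probe)) ","
                  else if (grepl(";", probe)) ";"
                  else ""
                },
                stop_nq("parse_error", sprintf("unknown dialect '%s'", dialect)))
  first <- strsplit(trimws(lines[[1]]), if (sep == "") "\\s+" else sep)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = has_header, strip.white = TRUE)
  if (ncol(df) < 2)
    stop_nq("parse_error", sprintf("'%s' does not have two columns", path))
  x <- suppressWarnings(as.numeric(df[[1]]))
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(x) || anyNA(y))
    stop_nq("parse_error", sprintf("non-numeric values in '%s'", path))
  tr <- polysome_trace(x, y, meta = meta)
  if (!tr$uniform_spacing) {
    if (resample) {
      xu <- seq(min(x), max(x), length.out = length(x))
      tr <- polysome_trace(xu, stats::approx(x, y, xout = xu)$y, meta = meta)
    } else {
      warning("non-uniform x spacing; pass resample = TRUE or integrate with method = 'trapezoid'")
    }
  }
  tr
}

#' Write a trace as two-column TSV (x, od260)
#'
#' @param trace a [polysome_trace].
#' @param path output path.
#' @param truth optional ground-truth list written to a JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, truth = NULL) {
  stopifnot(inherits(trace, "polysome_trace"))
  utils::write.table(data.frame(x = trace$x, od260 = trace$y), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# default smoothing window: 2% of the trace length, forced odd, >= 3
default_smooth_window <- function(n) {
  w <- max(3L, as.integer(round(0.02 * n)))
  if (w %% 2L == 0L) w + 1L else w
}

# leftmost argmin over an index range; errors if the segment is monotone
valley_between <- function(ys, from, to) {
  seg <- ys[from:to]
  d <- diff(seg)
  if (all(d <= 0) || all(d >= 0))
    stop_nq("no_valley", "segment between peaks is monotone; no valley to anchor on")
  from + which.min(seg) - 1L  # which.min takes the leftmost of a plateau
}

#' Locate the anchoring valleys of a polysome profile
#'
#' Peaks are detected on a centered moving-average smoothed copy of the
#' trace; the monosome is identified as the tallest peak (the 80S peak
#' dominates gradient profiles). The start anchor is the leftmost minimum
#' of the smoothed signal between the peak preceding the monosome (60S) and
#' the monosome; the monosome/disome anchor is the minimum between the
#' monosome and the next peak. Indices refer to the raw trace.
#'
#' @param trace a [polysome_trace].
#' @param smoothing_window moving-average window in samples (odd; default
#'   2\% of the trace length).
#' @return list: `anchor_start_idx`, `anchor_mono_di_idx`,
#'   `smoothing_window`, `monosome_idx`.
#' @export
find_anchor_valleys <- function(trace, smoothing_window = NULL) {
  stopifnot(inherits(trace, "polysome_trace"))
  n <- length(trace$y)
  if (is.null(smoothing_window)) smoothing_window <- default_smooth_window(n)
  ys <- smooth_ma(trace$y, smoothing_window)
  rng <- diff(range(ys))
  if (rng == 0) stop_nq("too_few_peaks", "flat trace: no peaks detectable")
  pk <- pracma::findpeaks(ys, minpeakheight = min(ys) + 0.02 * rng,
                          minpeakdistance = max(3L, smoothing_window))
  if (is.null(pk) || nrow(pk) < 3)
    stop_nq("too_few_peaks",
            "need at least 3 peaks (60S, 80S monosome, first polysome)")
  pos <- sort(pk[, 2])
  mono_i <- pos[which.max(ys[pos])]
  before <- pos[pos < mono_i]
  after <- pos[pos > mono_i]
  if (!length(before) || !length(after))
    stop_nq("too_few_peaks",
            "monosome peak must have a peak before (60S) and after (disome) it")
  prev_pk <- max(before)
  next_pk <- min(after)
  list(anchor_start_idx = as.integer(valley_between(ys, prev_pk, mono_i)),
       anchor_mono_di_idx = as.integer(valley_between(ys, mono_i, next_pk)),
       smoothing_window = as.integer(smoothing_window),
       monosome_idx = as.integer(mono_i))
}

#' Normalize a polysome trace at its anchors
#'
#' Y is min-max normalized over the whole sample (min -> 0, max -> 1); X is
#' affinely rescaled so the start anchor maps to 0 and the last datapoint
#' to 100. Points before the start anchor carry negative normalized X and
#' are excluded from fraction sums.
#'
#' @param trace a [polysome_trace].
#' @param anchors anchor list from [find_anchor_valleys()].
#' @return an object of class `normalized_trace` with `x_norm`, `y_norm`,
#'   `anchor_start_idx`, `anchor_mono_di_idx`, `smoothing_window`.
#' @export
normalize_trace <- function(trace, anchors = find_anchor_valleys(trace)) {
  stopifnot(inherits(trace, "polysome_trace"))
  rng <- range(trace$y)
  if (diff(rng) == 0)
    stop_nq("degenerate_trace", "constant trace cannot be min-max normalized")
  n <- length(trace$x)
  i0 <- anchors$anchor_start_idx
  if (anchors$anchor_mono_di_idx <= i0)
    stop_nq("invalid_spec", "mono/di anchor must come after the start anchor")
  x0 <- trace$x[i0]; x1 <- trace$x[n]
  structure(list(
    x_norm = (trace$x - x0) / (x1 - x0) * 100,
    y_norm = (trace$y - rng[1]) / diff(rng),
    anchor_start_idx = i0,
    anchor_mono_di_idx = anchors$anchor_mono_di_idx,
    smoothing_window = anchors$smoothing_window,
    uniform_spacing = trace$uniform_spacing
  ), class = "normalized_trace")
}

#' Monosome and polysome fractions and their ratio
#'
#' The monosome fraction is the sum of normalized Y from the start anchor
#' (X = 0) to the monosome/disome valley inclusive; the polysome fraction
#' is the sum from just after that valley to the last datapoint (X = 100).
#' The boundary sample belongs to the monosome window only. Points before
#' X = 0 (the 40S/60S region) enter neither fraction. A trapezoid variant
#' (on normalized X) is available for non-uniform spacing.
#'
#' @param norm a `normalized_trace`.
#' @param method `"sum"` (requires uniform spacing) or `"trapezoid"`.
#' @param boundary window that receives the valley sample, `"monosome"`
#'   (default) or `"polysome"`.
#' @return list of class `polysome_quant`: `monosome_fraction`,
#'   `polysome_fraction`, `pm_ratio`.
#' @export
integrate_fractions <- function(norm, method = c("sum", "trapezoid"),
                                boundary = c("monosome", "polysome")) {
  stopifnot(inherits(norm, "normalized_trace"))
  method <- match.arg(method)
  boundary <- match.arg(boundary)
  n <- length(norm$y_norm)
  i0 <- norm$anchor_start_idx
  i1 <- norm$anchor_mono_di_idx
  mono_idx <- if (boundary == "monosome") i0:i1 else i0:(i1 - 1L)
  poly_idx <- if (boundary == "monosome") seq(i1 + 1L, n) else seq(i1, n)
  if (length(mono_idx) < 2 || length(poly_idx) < 2 || i1 >= n)
    stop_nq("empty_window", "each fraction window needs at least 2 samples")
  if (method == "sum") {
    if (!isTRUE(norm$uniform_spacing))
      stop_nq("non_uniform_spacing",
              "sum-based fractions require uniform x spacing; use method = 'trapezoid'")
    mono <- sum(norm$y_norm[mono_idx])
    poly <- sum(norm$y_norm[poly_idx])
  } else {
    mono <- pracma::trapz(norm$x_norm[mono_idx], norm$y_norm[mono_idx])
    poly <- pracma::trapz(norm$x_norm[poly_idx], norm$y_norm[poly_idx])
  }
  if (mono <= 0) stop_nq("empty_window", "monosome fraction is not positive")
  structure(list(monosome_fraction = mono, polysome_fraction = poly,
                 pm_ratio = poly / mono),
            class = "polysome_quant")
}

#' @export
print.polysome_quant <- function(x, ...) {
  cat(sprintf("<polysome_quant> monosome = %.4g, polysome = %.4g, P/M = %.4g\n",
              x$monosome_fraction, x$polysome_fraction, x$pm_ratio))
  invisible(x)
}

#' Quantify a polysome trace end to end
#'
#' Convenience wrapper: anchors, normalization, fractions.
#'
#' @param trace a [polysome_trace].
#' @param smoothing_window see [find_anchor_valleys()].
#' @param ... passed to [integrate_fractions()].
#' @return a `polysome_quant`.
#' @export
quantify_polysome <- function(trace, smoothing_window = NULL, ...) {
  anchors <- find_anchor_valleys(trace, smoothing_window)
  integrate_fractions(normalize_trace(trace, anchors), ...)
}

#' Tabulate polysome/monosome ratios by condition
#'
#' @param samples data.frame with columns `sample`, `condition`, `pm_ratio`.
#' @return list with `samples` (input, conditions in order of first
#'   appearance) and `summary` (per-condition `n`, `mean`, `sd`).
#' @export
compare_profiles <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "condition", "pm_ratio") %in% names(samples)))
  if (!nrow(samples)) stop_nq("too_few_values", "no samples supplied")
  conds <- unique(samples$condition)
  summary <- do.call(rbind, lapply(conds, function(cc) {
    v <- samples$pm_ratio[samples$condition == cc]
    data.frame(condition = cc, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0)
  }))
  rownames(summary) <- NULL
  list(samples = samples, summary = summary)
}
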