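# Ground-truthed sucrose-gradient OD260 traces: a baseline plus one peak
# component per ribosomal species (40S, 60S, 80S monosome, disome, ...),
# with analytically known component areas so the polysome/monosome ratio
# has an exact truth value.

#' Specification of a synthetic polysome profile
#'
#' Components are rendered as area-parameterized Gaussian densities
#' (`area * dnorm(x, center, width)`) by default, or exponentially modified
#' Gaussians (`shape = "emg"`) to emulate the tailing of real gradient
#' peaks. Monosome truth is the `"80S"` component's area; polysome truth is
#' the summed area of every component sedimenting past it.
#'
#' @param peaks data.frame with columns `label`, `center`, `width`, `area`.
#'   Centers must be strictly increasing and must include an `"80S"` entry.
#' @param baseline constant offset added to the whole trace.
#' @param x_range length-2 numeric, gradient position range.
#' @param n_samples number of uniformly spaced samples (>= 50).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param shape peak shape, `"gaussian"` or `"emg"`.
#' @param emg_tau exponential tail constant for `shape = "emg"`.
#' @param seed integer RNG seed.
#' @return a list of class `trace_spec`.
#' @export
trace_spec <- function(peaks = default_polysome_peaks(),
                       baseline = 0.05,
                       x_range = c(0, 100),
                       n_samples = 600L,
                       noise_sd = 0.01,
                       shape = c("gaussian", "emg"),
                       emg_tau = 2,
                       seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(is.data.frame(peaks),
            all(c("label", "center", "width", "area") %in% names(peaks)))
  if (nrow(peaks) >= 2 && any(diff(peaks$center) <= 0))
    stop_nq("invalid_spec", "peak centers must be strictly increasing")
  if (any(peaks$width <= 0) || any(peaks$area < 0))
    stop_nq("invalid_spec", "peak widths must be positive and areas non-negative")
  if (!"80S" %in% peaks$label)
    stop_nq("invalid_spec", "peaks must include an '80S' (monosome) component")
  if (n_samples < 50L)
    stop_nq("invalid_spec", "n_samples must be >= 50")
  if (baseline < 0 || noise_sd < 0)
    stop_nq("invalid_spec", "baseline and noise_sd must be non-negative")
  structure(as.list(environment()), class = "trace_spec")
}

#' Default polysome profile components
#'
#' A typical cultured-cell profile: small 40S and 60S subunit peaks, a
#' dominant 80S monosome, and a decaying polysome series (disome to
#' 6-some). Gradient position runs 0-100 arbitrary units.
#'
#' @return data.frame of peak components (`label`, `center`, `width`, `area`).
#' @export
default_polysome_peaks <- function() {
  data.frame(
    label  = c("40S", "60S", "80S", "disome", "3-some", "4-some", "5-some", "6-some"),
    center = c(15,    24,    33,    45,       52,       58,       64,       70),
    width  = c(2,     2,     2.5,   2.5,      2.5,      2.5,      2.5,      2.5),
    area   = c(6,     10,    30,    12,       9,        7,        5,        3.5)
  )
}

#' Peak set with a chosen polysome/monosome truth ratio
#'
#' Scales the polysome component areas of [default_polysome_peaks()] so the
#' analytic polysome/monosome area ratio equals `true_ratio`. The area
#' factor is split evenly between peak amplitude and peak width
#' (`width * sqrt(f)`), mirroring how heavily loaded gradients broaden the
#' polysome region rather than growing a single sharp peak, and keeping the
#' 80S monosome the tallest peak of the profile.
#'
#' @param true_ratio target ratio of summed polysome area to 80S area.
#' @return data.frame of peak components.
#' @export
peaks_with_ratio <- function(true_ratio) {
  stopifnot(true_ratio >= 0)
  pk <- default_polysome_peaks()
  i80 <- match("80S", pk$label)
  poly <- seq_len(nrow(pk)) > i80
  cur <- sum(pk$area[poly]) / pk$area[i80]
  f <- true_ratio / cur
  pk$area[poly] <- pk$area[poly] * f
  pk$width[poly] <- pk$width[poly] * sqrt(f)
  pk
}

# EMG density with rate 1/tau (mean-shifted exponential tail)
demg <- function(x, mu, sigma, tau) {
  l <- 1 / tau
  arg <- (mu + l * sigma^2 - x) / (sqrt(2) * sigma)
  l / 2 * exp(l / 2 * (2 * mu + l * sigma^2 - 2 * x)) * pracma::erfc(arg)
}

#' Generate a ground-truthed polysome profile
#'
#' @param spec a [trace_spec].
#' @return a list with `trace` (a [polysome_trace]), `truth` (list:
#'   `A_monosome`, `A_polysome`, `true_ratio`), and `y_noiseless` (the
#'   rendered trace before noise, for oracle checks).
#' @export
gen_polysome_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  x <- seq(spec$x_range[1], spec$x_range[2], length.out = spec$n_samples)
  y0 <- rep(spec$baseline, spec$n_samples)
  for (i in seq_len(nrow(spec$peaks))) {
    p <- spec$peaks[i, ]
    comp <- if (spec$shape == "gaussian")
      p$area * stats::dnorm(x, p$center, p$width)
    else
      p$area * demg(x, p$center, p$width, spec$emg_tau)
    y0 <- y0 + comp
  }
  y <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) pmax(0, y0 + stats::rnorm(length(y0), 0, spec$noise_sd))
    else y0
  })
  i80 <- match("80S", spec$peaks$label)
  a_mono <- spec$peaks$area[i80]
  a_poly <- if (i80 < nrow(spec$peaks)) sum(spec$peaks$area[(i80 + 1):nrow(spec$peaks)]) else 0
  true_ratio <- if (a_mono > 0) a_poly / a_mono else NA_real_
  list(
    trace = polysome_trace(x, y, meta = list(source = "synthetic", seed = spec$seed)),
    truth = list(A_monosome = a_mono, A_polysome = a_poly, true_ratio = true_ratio),
    y_noiseless = y0
  )
}
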