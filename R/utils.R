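# Internal helpers: error conditions, seeded RNG scopes, thresholding,
# rasterization primitives shared by the generators and the analysis code.

#' Signal a classed nucleoquant error
#'
#' All package errors carry a class of the form `nucleoquant_<id>` (plus
#' `nucleoquant_error`) so callers can branch on the failure mode rather
#' than on message text.
#'
#' @param id short identifier, e.g. "channel_not_found".
#' @param msg human-readable message.
#' @param ... fields stored on the condition object.
#' @noRd
stop_nq <- function(id, msg, ...) {
  cnd <- structure(
    class = c(paste0("nucleoquant_", id), "nucleoquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

#' Evaluate an expression with a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are
#' deterministic in their `seed` field without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance on a fixed-bin histogram. Returns a
#' value such that `v > threshold` selects the bright class. For a constant
#' vector the single value is returned (nothing exceeds it).
#'
#' @param v numeric vector of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold on the intensity scale of `v`.
#' @keywords internal
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  bin <- pmin(n_bins, floor((v - r[1]) / diff(r) * n_bins) + 1L)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / n_bins * diff(r)
}

#' Logical disk mask over pixel centers
#'
#' Pixel (row, col) belongs to the disk when its center lies within
#' radius `r` of (`cy`, `cx`). Rows index the first matrix dimension.
#' @noRd
disk_mask <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

#' Stamp a disk into a label matrix (bounding-box limited)
#' @noRd
stamp_disk <- function(labels, cy, cx, r, value) {
  h <- nrow(labels); w <- ncol(labels)
  r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
  rows <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cols <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  inside <- (rows - cy)^2 + (cols - cx)^2 <= r^2
  sub <- labels[r0:r1, c0:c1]
  sub[inside] <- value
  labels[r0:r1, c0:c1] <- sub
  labels
}

#' Relabel objects 1..N in raster (row-major) order of their first pixel
#' @noRd
relabel_raster <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(matrix(0L, nrow(labels), ncol(labels)))
  h <- nrow(labels); w <- ncol(labels)
  rows <- row(labels); cols <- col(labels)
  raster_idx <- (rows - 1L) * w + cols
  first <- vapply(ids, function(k) min(raster_idx[labels == k]), numeric(1))
  ord <- ids[order(first)]
  out <- matrix(0L, h, w)
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}

#' Permutation old label -> raster-order label (labels must be 1..N)
#' @noRd
relabel_map <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(integer(0))
  w <- ncol(labels)
  raster_idx <- (row(labels) - 1L) * w + col(labels)
  first <- vapply(ids, function(k) min(raster_idx[labels == k]), numeric(1))
  map <- integer(max(ids))
  map[ids[order(first)]] <- seq_along(ids)
  map
}

#' Apply a label permutation to a label matrix
#' @noRd
apply_relabel <- function(labels, map) {
  out <- labels
  sel <- labels > 0
  out[sel] <- map[labels[sel]]
  out
}

#' Centered moving-average smoothing with shrinking edge windows
#'
#' Window is forced odd; near the edges the window shrinks symmetrically so
#' the output has no phase shift and the same length as the input.
#' @noRd
smooth_ma <- function(y, window) {
  n <- length(y)
  window <- as.integer(window)
  if (window < 1L) window <- 1L
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L || n < 3L) return(y)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  # shrink symmetrically so the window stays centered
  k <- pmin(idx - lo, hi - idx)
  lo <- idx - k; hi <- idx + k
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Outline pixels of labeled objects (4-neighbour label changes)
#' @noRd
label_outlines <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  pad <- matrix(-1L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- labels
  ctr <- labels
  up <- pad[1:h, 2:(w + 1L)]
  dn <- pad[3:(h + 2L), 2:(w + 1L)]
  lf <- pad[2:(h + 1L), 1:w]
  rt <- pad[2:(h + 1L), 3:(w + 2L)]
  (ctr > 0) & (up != ctr | dn != ctr | lf != ctr | rt != ctr)
}

#' Rescale a numeric vector or matrix to [0, 1]; constant input maps to 0
#' @noRd
stretch01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) return(x * 0)
  (x - r[1]) / diff(r)
}
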