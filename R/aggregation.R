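# PolyQ-EGFP aggregation scoring: cells grown from nuclear seeds on the
# EGFP channel, per-cell gray-level co-occurrence (Haralick) contrast,
# multi-scale Laplacian-of-Gaussian focus counting, and the S0/S1/S2
# classification (no aggregates / 1-5 aggregates / more than 5).

#' Grow cells around nuclear seeds
#'
#' Each nucleus is expanded into the above-threshold region of the signal
#' channel by seeded propagation (Voronoi-like region growing regularized
#' by intensity, the standard secondary-object strategy). The threshold is
#' a global Otsu computed on log-transformed intensities (`log1p`), which
#' keeps a few very bright aggregate pixels from pulling the threshold
#' above the diffuse cytoplasmic signal; pixels below it stay unassigned.
#' Nuclear pixels always belong to their own cell, so when nothing exceeds
#' the threshold each cell falls back to its nucleus footprint. Cell labels
#' equal their seed nucleus labels.
#'
#' @param image a [multichannel_image].
#' @param signal_channel channel carrying the cytoplasmic signal (EGFP).
#' @param nuclei seed [label_mask]; must contain at least one object.
#' @param lambda regularization of the propagation metric: larger values
#'   weigh Euclidean distance over intensity differences.
#' @return a [label_mask] of cells with an identity `parent_map` to nuclei.
#' @export
segment_cells <- function(image, signal_channel = "egfp", nuclei, lambda = 0.05) {
  sig <- channel(image, signal_channel)
  stopifnot(inherits(nuclei, "label_mask"))
  check_aligned(image, nuclei)
  if (n_objects(nuclei) == 0)
    stop_nq("no_seeds", "nuclei mask contains no objects to seed cells from")
  lsig <- log1p(sig)
  mask <- lsig > otsu_threshold(lsig) | nuclei$labels > 0
  lab <- EBImage::propagate(sig, nuclei$labels, mask = mask, lambda = lambda)
  lab <- matrix(as.integer(lab), nrow(sig), ncol(sig))
  ids <- sort(unique(lab[lab > 0]))
  label_mask(lab, parent_map = stats::setNames(ids, ids))
}

#' Texture parameters for co-occurrence contrast
#'
#' @param gray_levels number of quantization levels (>= 2); intensities are
#'   min-max quantized per object, so contrast is invariant to affine
#'   rescaling of a cell's intensities.
#' @param offset_distance_px pixel offset between co-occurring pairs.
#' @param directions subset of `c(0, 45, 90, 135)` degrees; the contrast is
#'   averaged over them.
#' @return a list of class `texture_params`.
#' @export
texture_params <- function(gray_levels = 64L, offset_distance_px = 1L,
                           directions = c(0, 45, 90, 135)) {
  if (gray_levels < 2) stop_nq("invalid_spec", "gray_levels must be >= 2")
  if (offset_distance_px < 1) stop_nq("invalid_spec", "offset_distance_px must be >= 1")
  directions <- unique(directions)
  if (!length(directions) || !all(directions %in% c(0, 45, 90, 135)))
    stop_nq("invalid_spec", "directions must be a non-empty subset of {0, 45, 90, 135}")
  structure(list(gray_levels = as.integer(gray_levels),
                 offset_distance_px = as.integer(offset_distance_px),
                 directions = directions),
            class = "texture_params")
}

# row/col offsets per direction (image convention: 0 deg = horizontal)
direction_offset <- function(deg, d) {
  switch(as.character(deg),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d))
}

#' Per-cell gray-level co-occurrence contrast
#'
#' For each labeled object the signal intensities are min-max quantized to
#' `gray_levels` bins, a symmetric normalized co-occurrence matrix P is
#' accumulated over in-object pixel pairs at the given offset for each
#' direction, and the Haralick contrast `sum_(i,j) (i-j)^2 P(i,j)` is
#' averaged over directions. Diffuse (smooth) signal yields low contrast;
#' bright aggregates next to dim cytoplasm yield high contrast. Objects
#' with zero intensity range return 0.
#'
#' @param image a [multichannel_image].
#' @param signal_channel channel to quantify.
#' @param cells cell [label_mask].
#' @param params a [texture_params].
#' @return data.frame: `cell_id`, `glcm_contrast`.
#' @export
glcm_contrast <- function(image, signal_channel = "egfp", cells,
                          params = texture_params()) {
  sig <- channel(image, signal_channel)
  check_aligned(image, cells)
  ids <- sort(unique(cells$labels[cells$labels > 0]))
  L <- params$gray_levels
  d <- params$offset_distance_px
  vals <- vapply(ids, function(i) {
    px <- which(cells$labels == i)
    h <- nrow(sig)
    rows <- (px - 1L) %% h + 1L
    cols <- (px - 1L) %/% h + 1L
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    obj <- cells$labels[r0:r1, c0:c1, drop = FALSE] == i
    if (sum(obj) < 2)
      stop_nq("degenerate_object",
              sprintf("cell %d has no valid pixel pair at the requested offset", i))
    v <- sig[r0:r1, c0:c1, drop = FALSE]
    rng <- range(v[obj])
    if (diff(rng) == 0) return(0)
    q <- matrix(0L, nrow(obj), ncol(obj))
    q[obj] <- pmin(L, floor((v[obj] - rng[1]) / diff(rng) * L) + 1L)
    total <- 0; n_dir <- 0L
    for (deg in params$directions) {
      off <- direction_offset(deg, d)
      nr <- nrow(q); nc <- ncol(q)
      rs <- seq_len(nr); cs <- seq_len(nc)
      rs1 <- rs[rs + off[1] >= 1 & rs + off[1] <= nr]
      cs1 <- cs[cs + off[2] >= 1 & cs + off[2] <= nc]
      if (!length(rs1) || !length(cs1)) next
      a <- q[rs1, cs1, drop = FALSE]
      b <- q[rs1 + off[1], cs1 + off[2], drop = FALSE]
      ok <- a > 0L & b > 0L
      if (!any(ok)) next
      # symmetric P: mean squared level difference over ordered pairs equals
      # the contrast of the symmetrized normalized matrix
      total <- total + mean((a[ok] - b[ok])^2)
      n_dir <- n_dir + 1L
    }
    if (n_dir == 0L)
      stop_nq("degenerate_object",
              sprintf("cell %d has no valid pixel pair at the requested offset", i))
    total / n_dir
  }, numeric(1))
  data.frame(cell_id = ids, glcm_contrast = vals)
}

# scale-normalized LoG response stack (one matrix per sigma), computed by
# separable convolution of the blurred image
log_response <- function(img, sigma) {
  ks <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  half <- (ks - 1L) %/% 2L
  xx <- matrix(rep(-half:half, each = ks), ks, ks)
  yy <- t(xx)
  g <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
  g <- g / sum(g)
  log_k <- ((xx^2 + yy^2 - 2 * sigma^2) / sigma^4) * g
  log_k <- log_k - mean(log_k)  # zero response to constant regions
  -sigma^2 * EBImage::filter2(img, log_k, boundary = "replicate")
}

gaussian_blur <- function(img, sigma) {
  ks <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  half <- (ks - 1L) %/% 2L
  xx <- matrix(rep(-half:half, each = ks), ks, ks)
  g <- exp(-(xx^2 + t(xx)^2) / (2 * sigma^2))
  EBImage::filter2(img, g / sum(g), boundary = "replicate")
}

local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  res <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (m >= pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  res & is.finite(m)
}

#' Count aggregate foci per cell
#'
#' Bright puncta are detected as local maxima of the scale-normalized
#' Laplacian-of-Gaussian response over a small scale range, within each
#' cell. A candidate is retained when its Gaussian-smoothed peak intensity
#' exceeds the cell's median intensity by at least
#' `min_prominence * (in-cell intensity range)`; overlapping detections
#' across scales are suppressed, keeping the strongest.
#'
#' @param image a [multichannel_image].
#' @param signal_channel channel to search.
#' @param cells cell [label_mask].
#' @param min_prominence fraction of the in-cell intensity range a focus
#'   must rise above the cell's median intensity.
#' @param focus_scale_px length-2 `c(min, max)` focus radius range, pixels.
#' @param n_scales number of logarithmically spaced detection scales.
#' @return data.frame: `cell_id`, `foci_count`.
#' @export
detect_foci <- function(image, signal_channel = "egfp", cells,
                        min_prominence = 0.3, focus_scale_px = c(2, 5),
                        n_scales = 4L) {
  stopifnot(length(focus_scale_px) == 2, all(focus_scale_px > 0),
            focus_scale_px[1] < focus_scale_px[2])
  sig <- channel(image, signal_channel)
  check_aligned(image, cells)
  ids <- sort(unique(cells$labels[cells$labels > 0]))
  if (!length(ids)) return(data.frame(cell_id = integer(0), foci_count = integer(0)))
  sigmas <- exp(seq(log(focus_scale_px[1] / sqrt(2)),
                    log(focus_scale_px[2] / sqrt(2)), length.out = n_scales))
  resp <- lapply(sigmas, function(s) log_response(sig, s))
  blur <- lapply(sigmas, function(s) gaussian_blur(sig, s))
  # candidates: spatial local maxima that also dominate adjacent scales
  cand <- NULL
  for (si in seq_along(sigmas)) {
    lm <- local_maxima(resp[[si]]) & resp[[si]] > 0 & cells$labels > 0
    if (n_scales > 1) {
      if (si > 1) lm <- lm & resp[[si]] >= resp[[si - 1]]
      if (si < n_scales) lm <- lm & resp[[si]] >= resp[[si + 1]]
    }
    idx <- which(lm)
    if (length(idx))
      cand <- rbind(cand, data.frame(
        idx = idx, scale = si, response = resp[[si]][idx],
        smoothed = blur[[si]][idx], cell = cells$labels[idx]))
  }
  counts <- stats::setNames(integer(length(ids)), ids)
  if (!is.null(cand) && nrow(cand)) {
    h <- nrow(sig)
    cand$row <- (cand$idx - 1L) %% h + 1L
    cand$col <- (cand$idx - 1L) %/% h + 1L
    for (i in ids) {
      cpx <- sig[cells$labels == i]
      rng <- diff(range(cpx))
      if (rng == 0) next
      bg <- stats::median(cpx)
      cc <- cand[cand$cell == i & cand$smoothed - bg >= min_prominence * rng, ,
                 drop = FALSE]
      if (!nrow(cc)) next
      cc <- cc[order(-cc$response), , drop = FALSE]
      kept_r <- kept_c <- numeric(0)
      sep <- max(2, focus_scale_px[1])
      for (j in seq_len(nrow(cc))) {
        if (!length(kept_r) ||
            all((cc$row[j] - kept_r)^2 + (cc$col[j] - kept_c)^2 > sep^2)) {
          kept_r <- c(kept_r, cc$row[j]); kept_c <- c(kept_c, cc$col[j])
        }
      }
      counts[as.character(i)] <- length(kept_r)
    }
  }
  data.frame(cell_id = ids, foci_count = as.integer(counts))
}

#' Assign S0/S1/S2 aggregation scores
#'
#' Adds a `score` column from `foci_count`: `S0` for 0 aggregates, `S1` for
#' 1-5, `S2` for more than 5.
#'
#' @param measures data.frame with a `foci_count` column.
#' @return the input with a `score` character column appended.
#' @export
score_cells <- function(measures) {
  stopifnot(is.data.frame(measures), "foci_count" %in% names(measures))
  measures$score <- score_from_count(measures$foci_count)
  measures
}

#' Full per-cell aggregation record
#'
#' Composes [glcm_contrast()], [detect_foci()] and [score_cells()] into one
#' table with cell geometry and integrated EGFP signal. Cells whose
#' integrated signal falls below `min_egfp` (EGFP-negative cells) are
#' dropped before scoring.
#'
#' @param image a [multichannel_image].
#' @param signal_channel channel to quantify.
#' @param cells cell [label_mask] from [segment_cells()].
#' @param texture a [texture_params].
#' @param min_prominence,focus_scale_px see [detect_foci()].
#' @param min_egfp minimum integrated signal for a cell to be scored.
#' @return data.frame: `cell_id`, `nucleus_id`, `cell_area_px`,
#'   `egfp_integrated`, `glcm_contrast`, `foci_count`, `score`.
#' @export
measure_cells <- function(image, signal_channel = "egfp", cells,
                          texture = texture_params(), min_prominence = 0.3,
                          focus_scale_px = c(2, 5), min_egfp = 0) {
  sig <- channel(image, signal_channel)
  check_aligned(image, cells)
  ids <- sort(unique(cells$labels[cells$labels > 0]))
  geom <- data.frame(
    cell_id = ids,
    nucleus_id = if (is.null(cells$parent_map)) ids
                 else as.integer(cells$parent_map[as.character(ids)]),
    cell_area_px = vapply(ids, function(i) sum(cells$labels == i), integer(1)),
    egfp_integrated = vapply(ids, function(i) sum(sig[cells$labels == i]), numeric(1))
  )
  out <- merge(geom, glcm_contrast(image, signal_channel, cells, texture),
               by = "cell_id")
  out <- merge(out, detect_foci(image, signal_channel, cells,
                                min_prominence, focus_scale_px),
               by = "cell_id")
  out <- out[out$egfp_integrated >= min_egfp, , drop = FALSE]
  rownames(out) <- NULL
  score_cells(out)
}

#' Per-condition texture summaries and rank test
#'
#' Summarizes per-cell contrast values by condition (n, median, quartiles)
#' and, for two conditions, compares them with a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test.
#'
#' @param measures data.frame with a contrast column and a condition column.
#' @param value_col name of the value column (default `"glcm_contrast"`).
#' @param condition_col name of the condition column.
#' @return list with `summary` (data.frame: `condition`, `n`, `median`,
#'   `q1`, `q3`) and, when exactly two conditions are present, `p_value`.
#' @export
texture_distribution <- function(measures, value_col = "glcm_contrast",
                                 condition_col = "condition") {
  stopifnot(is.data.frame(measures),
            all(c(value_col, condition_col) %in% names(measures)))
  conds <- unique(measures[[condition_col]])
  groups <- lapply(conds, function(cc)
    measures[[value_col]][measures[[condition_col]] == cc])
  ns <- lengths(groups)
  if (any(ns < 2))
    stop_nq("too_few_cells", "each condition needs at least 2 cells")
  summary <- data.frame(
    condition = conds,
    n = ns,
    median = vapply(groups, stats::median, numeric(1)),
    q1 = vapply(groups, function(v) stats::quantile(v, 0.25, names = FALSE), numeric(1)),
    q3 = vapply(groups, function(v) stats::quantile(v, 0.75, names = FALSE), numeric(1))
  )
  out <- list(summary = summary)
  if (length(conds) == 2) {
    out$p_value <- suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], exact = NULL)$p.value)
    out$test <- "two-sided Mann-Whitney"
  }
  out
}
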