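# Nucleolar morphometry: nucleus segmentation on the DNA channel, nucleolus
# segmentation on the marker channel masked by nuclei (with merging of
# adjacent fragments), and per-nucleus size/intensity statistics, including
# the nascent-RNA (FUrd) channel variant.

#' Segment nuclei from the DNA channel
#'
#' Global Otsu threshold on the DNA channel, hole filling, connected-
#' component labeling (4-connectivity), removal of objects below
#' `min_area_px` and, optionally, of objects touching the image border.
#' Surviving objects are relabeled 1..N in raster (row-major) order of
#' their first pixel.
#'
#' @param image a [multichannel_image].
#' @param dna_channel name of the DNA-stain channel.
#' @param min_area_px minimum object area in pixels.
#' @param exclude_border drop objects touching any image edge
#'   (default `TRUE`, the usual convention for per-cell statistics).
#' @return a [label_mask] of nuclei.
#' @export
segment_nuclei <- function(image, dna_channel = "dna", min_area_px = 80L,
                           exclude_border = TRUE) {
  stopifnot(min_area_px >= 1)
  dna <- channel(image, dna_channel)
  thr <- otsu_threshold(dna)
  fg <- dna > thr
  if (!any(fg)) return(label_mask(matrix(0L, nrow(dna), ncol(dna))))
  filled <- EBImage::fillHull(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  lab <- EBImage::bwlabel(filled)
  lab <- matrix(as.integer(lab), nrow(dna), ncol(dna))
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < min_area_px)
  if (exclude_border) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, edge[edge > 0])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  label_mask(relabel_raster(lab))
}

#' Segment nucleoli within nuclei
#'
#' Candidate nucleoli are called by a per-nucleus Otsu threshold on the
#' marker channel (robust to between-cell brightness differences); pixels
#' outside any nucleus are discarded. A nucleus whose bright class is not
#' enriched at least `min_enrichment`-fold over its dim class yields no
#' candidates (guards against splitting pure noise). Candidate objects
#' whose boundaries lie within `merge_distance_px` of each other are merged
#' into a single object (dilate-union-relabel), and each final object is
#' assigned the parent nucleus containing its centroid; objects whose
#' centroid falls outside every nucleus are dropped.
#'
#' @param image a [multichannel_image].
#' @param marker_channel name of the nucleolar marker channel.
#' @param nuclei nucleus [label_mask] from [segment_nuclei()].
#' @param merge_distance_px maximum boundary gap (pixels) for two fragments
#'   to count as one nucleolus.
#' @param min_area_px minimum nucleolus area in pixels.
#' @param min_enrichment minimum bright/dim mean-intensity ratio for a
#'   nucleus to be considered to contain nucleolar signal.
#' @return a [label_mask] of nucleoli with `parent_map` into `nuclei`.
#' @export
segment_nucleoli <- function(image, marker_channel = "marker", nuclei,
                             merge_distance_px = 2L, min_area_px = 4L,
                             min_enrichment = 1.2) {
  marker <- channel(image, marker_channel)
  stopifnot(inherits(nuclei, "label_mask"))
  check_aligned(image, nuclei)
  h <- nrow(marker); w <- ncol(marker)
  cand <- matrix(FALSE, h, w)
  for (i in seq_len(max(nuclei$labels, 0))) {
    px <- nuclei$labels == i
    if (!any(px)) next
    v <- marker[px]
    thr <- otsu_threshold(v)
    hi <- v > thr
    if (!any(hi) || all(hi)) next
    if (mean(v[hi]) < min_enrichment * mean(v[!hi])) next
    cand[px] <- marker[px] > thr
  }
  if (!any(cand))
    return(label_mask(matrix(0L, h, w),
                      parent_map = NULL))
  # merge fragments whose boundary gap <= merge_distance_px: dilating both
  # fragments by ceiling(m/2) closes a gap of at most m, so labeling the
  # dilated union groups exactly the fragments to merge
  if (merge_distance_px > 0) {
    r <- as.integer(ceiling(merge_distance_px / 2))
    kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    dil <- EBImage::dilate(matrix(as.numeric(cand), h, w), kern)
    groups <- EBImage::bwlabel(dil)
  } else {
    groups <- EBImage::bwlabel(matrix(as.numeric(cand), h, w))
  }
  lab <- matrix(0L, h, w)
  lab[cand] <- as.integer(groups)[cand]
  # enforce min area, then assign parents by centroid containment
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < min_area_px)
  if (length(small)) lab[lab %in% small] <- 0L
  lab <- relabel_raster(lab)
  ids <- sort(unique(lab[lab > 0]))
  parent <- integer(0)
  for (k in ids) {
    px <- which(lab == k)
    cy <- mean((px - 1L) %% h + 1L)
    cx <- mean((px - 1L) %/% h + 1L)
    p <- nuclei$labels[round(cy), round(cx)]
    if (p == 0L) {
      lab[px] <- 0L  # centroid outside every nucleus: drop
    } else {
      parent[as.character(k)] <- p
    }
  }
  lab <- relabel_raster(lab)
  # relabeling preserved raster order, so remap parent names accordingly
  if (length(parent)) {
    kept <- sort(as.integer(names(parent)))
    parent <- stats::setNames(parent[as.character(kept)], seq_along(kept))
  }
  label_mask(lab, parent_map = if (length(parent)) parent else NULL)
}

#' Per-nucleus morphometry and marker intensity statistics
#'
#' For every nucleus: the number of child nucleoli, total nucleolar area,
#' the nucleolar/nuclear area ratio (`size_fold`), mean/median/integrated
#' marker intensity over nucleolar pixels, mean marker intensity over the
#' nucleoplasm (nuclear pixels minus nucleolar pixels), and the presence
#' ratio (nucleolar mean / nucleoplasmic mean; `NA` when the nucleus has no
#' nucleoli or no nucleoplasm). A `qc_pass` flag marks nuclei with solidity
#' >= 0.8 and area at most twice the 99th percentile, an automated stand-in
#' for manual curation of badly segmented cells.
#'
#' @param image a [multichannel_image].
#' @param marker_channel channel to measure.
#' @param nuclei nucleus [label_mask].
#' @param nucleoli nucleolus [label_mask] carrying a `parent_map` into
#'   `nuclei`.
#' @return data.frame with one row per nucleus: `nucleus_id`,
#'   `nuclear_area_px`, `nucleolus_count`, `nucleolar_area_px`, `size_fold`,
#'   `marker_nucleolar_mean`, `marker_nucleolar_median`,
#'   `marker_nucleolar_integrated`, `marker_nucleoplasm_mean`,
#'   `presence_ratio`, `qc_pass`.
#' @export
measure_nuclei <- function(image, marker_channel = "marker", nuclei, nucleoli) {
  marker <- channel(image, marker_channel)
  check_aligned(image, nuclei)
  check_aligned(image, nucleoli)
  ids <- sort(unique(nuclei$labels[nuclei$labels > 0]))
  pm <- nucleoli$parent_map
  res <- lapply(ids, function(i) {
    nuc_px <- nuclei$labels == i
    kids <- if (is.null(pm)) integer(0) else as.integer(names(pm)[pm == i])
    nlo_px <- nuc_px & (nucleoli$labels %in% kids) & nucleoli$labels > 0
    plasm_px <- nuc_px & !nlo_px
    n_nlo <- sum(nlo_px)
    data.frame(
      nucleus_id = i,
      nuclear_area_px = sum(nuc_px),
      nucleolus_count = length(kids),
      nucleolar_area_px = n_nlo,
      size_fold = n_nlo / sum(nuc_px),
      marker_nucleolar_mean = if (n_nlo) mean(marker[nlo_px]) else NA_real_,
      marker_nucleolar_median = if (n_nlo) stats::median(marker[nlo_px]) else NA_real_,
      marker_nucleolar_integrated = if (n_nlo) sum(marker[nlo_px]) else 0,
      marker_nucleoplasm_mean = if (any(plasm_px)) mean(marker[plasm_px]) else NA_real_,
      presence_ratio = if (n_nlo && any(plasm_px))
        mean(marker[nlo_px]) / mean(marker[plasm_px]) else NA_real_,
      qc_pass = NA  # filled below (needs the area distribution)
    )
  })
  out <- do.call(rbind, res)
  if (nrow(out)) {
    solidity <- vapply(ids, function(i) object_solidity(nuclei$labels == i), numeric(1))
    area_cap <- 2 * stats::quantile(out$nuclear_area_px, 0.99, names = FALSE)
    out$qc_pass <- solidity >= 0.8 & out$nuclear_area_px <= area_cap
  }
  rownames(out) <- NULL
  out
}

# area / convex-hull area of a pixel set
object_solidity <- function(px_mask) {
  idx <- which(px_mask)
  if (length(idx) < 3) return(1)
  h <- nrow(px_mask)
  ys <- (idx - 1L) %% h + 1L
  xs <- (idx - 1L) %/% h + 1L
  pts <- cbind(xs, ys)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(1)
  j <- c(2:n, 1)
  hull_area <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
  # pixel-center hull underestimates the rasterized area; pad by a half-pixel
  # band along the hull perimeter
  per <- sum(sqrt(rowSums((hp[j, , drop = FALSE] - hp)^2)))
  min(1, length(idx) / (hull_area + per / 2 + 1))
}

#' Nascent-RNA (FUrd) signal inside nucleoli
#'
#' The same measurement geometry as [measure_nuclei()], read on the FUrd
#' channel: per nucleus, the integrated and median FUrd intensity over its
#' nucleolar pixels.
#'
#' @param image a [multichannel_image].
#' @param furd_channel name of the FUrd channel.
#' @param nuclei,nucleoli aligned [label_mask]s, `nucleoli` with a
#'   `parent_map` into `nuclei`.
#' @return data.frame: `nucleus_id`, `furd_nucleolar_integrated`,
#'   `furd_nucleolar_median`.
#' @export
measure_nascent_rna <- function(image, furd_channel = "furd", nuclei, nucleoli) {
  furd <- channel(image, furd_channel)
  check_aligned(image, nuclei)
  check_aligned(image, nucleoli)
  ids <- sort(unique(nuclei$labels[nuclei$labels > 0]))
  pm <- nucleoli$parent_map
  res <- lapply(ids, function(i) {
    kids <- if (is.null(pm)) integer(0) else as.integer(names(pm)[pm == i])
    nlo_px <- (nuclei$labels == i) & (nucleoli$labels %in% kids) & nucleoli$labels > 0
    data.frame(
      nucleus_id = i,
      furd_nucleolar_integrated = if (any(nlo_px)) sum(furd[nlo_px]) else 0,
      furd_nucleolar_median = if (any(nlo_px)) stats::median(furd[nlo_px]) else NA_real_
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quality-control overlay image
#'
#' A contrast-stretched grayscale composite of all channels with nucleus
#' outlines in yellow and nucleolus outlines in magenta, for visual
#' verification of the segmentation.
#'
#' @param image a [multichannel_image].
#' @param nuclei,nucleoli aligned [label_mask]s.
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
qc_overlay <- function(image, nuclei, nucleoli = NULL) {
  check_aligned(image, nuclei)
  if (!is.null(nucleoli)) check_aligned(image, nucleoli)
  d <- dim(image$pixels)
  base <- stretch01(apply(image$pixels, c(1, 2), mean))
  rgb <- array(rep(base, 3L), c(d[1], d[2], 3L))
  nuc_out <- label_outlines(nuclei$labels)
  rgb[, , 1][nuc_out] <- 1; rgb[, , 2][nuc_out] <- 1; rgb[, , 3][nuc_out] <- 0
  if (!is.null(nucleoli)) {
    nlo_out <- label_outlines(nucleoli$labels)
    rgb[, , 1][nlo_out] <- 1; rgb[, , 2][nlo_out] <- 0; rgb[, , 3][nlo_out] <- 1
  }
  rgb
}
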