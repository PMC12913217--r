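# Ground-truthed synthetic micrographs: nucleolar scenes (DNA + nucleolar
# marker channels) and polyQ-EGFP aggregation scenes (DNA + EGFP channels).
# Objects are rasterized as hard-edged disks so every truth quantity is an
# exact pixel count on the internal label rendering; additive Gaussian noise
# (clipped at zero) is applied afterwards.

#' Specification of a synthetic nucleolar scene
#'
#' Defaults emulate cultured-cell fields stained with a DNA dye and a
#' nucleolar marker (NCL/FBL or FUrd): non-touching nuclei away from the
#' image border, each containing 0-4 bright nucleoli enriched over the
#' nucleoplasm.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_px length-2 vector `c(mean, sd)` of nuclear radii.
#' @param nucleoli_per_nucleus probability vector over counts 0..6
#'   (normalized internally).
#' @param nucleolus_radius_px length-2 vector `c(mean, sd)` of nucleolar radii.
#' @param nucleolus_gap_px minimum boundary gap between sibling nucleoli.
#' @param nucleoplasm_intensity marker intensity over the nucleoplasm.
#' @param nucleolar_enrichment ratio of nucleolar to nucleoplasmic marker
#'   intensity; must be >= 1.
#' @param dna_intensity DNA-channel intensity added inside nuclei.
#' @param background_intensity intensity outside all objects (both channels).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed; identical spec + seed reproduces the scene
#'   bit for bit.
#' @return a list of class `nucleolar_scene_spec`.
#' @export
nucleolar_scene_spec <- function(image_height_px = 512L, image_width_px = 512L,
                                 n_nuclei = 25L,
                                 nucleus_radius_px = c(mean = 18, sd = 2),
                                 nucleoli_per_nucleus = c(`0` = 0.10, `1` = 0.25,
                                                          `2` = 0.30, `3` = 0.25,
                                                          `4` = 0.10, `5` = 0, `6` = 0),
                                 nucleolus_radius_px = c(mean = 4, sd = 0.7),
                                 nucleolus_gap_px = 3,
                                 nucleoplasm_intensity = 40,
                                 nucleolar_enrichment = 3,
                                 dna_intensity = 80,
                                 background_intensity = 5,
                                 noise_sd = 2,
                                 seed = 1L) {
  if (nucleolar_enrichment < 1)
    stop_nq("invalid_spec", "nucleolar_enrichment must be >= 1")
  if (length(nucleoli_per_nucleus) != 7 || any(nucleoli_per_nucleus < 0) ||
      sum(nucleoli_per_nucleus) <= 0)
    stop_nq("invalid_spec", "nucleoli_per_nucleus must be 7 non-negative weights over counts 0..6")
  if (any(c(nucleoplasm_intensity, dna_intensity, background_intensity, noise_sd) < 0))
    stop_nq("invalid_spec", "intensities and noise_sd must be non-negative")
  if (n_nuclei < 0 || nucleus_radius_px[1] <= 0 || nucleolus_radius_px[1] <= 0)
    stop_nq("invalid_spec", "counts and radii must be positive")
  structure(as.list(environment()), class = "nucleolar_scene_spec")
}

# rejection-sampled non-overlapping disk centers with a boundary gap;
# errors with placement_infeasible after bounded retries
place_disks <- function(h, w, radii, gap = 2, border = 2, max_tries = 500L,
                        what = "object") {
  n <- length(radii)
  cy <- cx <- numeric(n)
  for (i in seq_len(n)) {
    lo_y <- radii[i] + border; hi_y <- h - radii[i] - border + 1
    lo_x <- radii[i] + border; hi_x <- w - radii[i] - border + 1
    if (lo_y >= hi_y || lo_x >= hi_x)
      stop_nq("placement_infeasible",
              sprintf("%s radius %.1f does not fit a %d x %d image", what, radii[i], h, w))
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      yy <- stats::runif(1, lo_y, hi_y)
      xx <- stats::runif(1, lo_x, hi_x)
      if (i == 1L) { placed <- TRUE }
      else {
        j <- seq_len(i - 1L)
        placed <- all((yy - cy[j])^2 + (xx - cx[j])^2 >
                        (radii[i] + radii[j] + gap)^2)
      }
      if (placed) { cy[i] <- yy; cx[i] <- xx; break }
    }
    if (!placed)
      stop_nq("placement_infeasible",
              sprintf("could not place %s %d of %d without overlap after %d tries",
                      what, i, n, max_tries))
  }
  data.frame(cy = cy, cx = cx, r = radii)
}

# Non-overlapping disk centers inside a parent disk (whole-set restarts).
# `gap` is the guaranteed minimum empty-pixel gap between the rasterized
# disks: the center-distance constraint carries a 1-px margin because a
# continuous gap of width g only guarantees g-1 empty pixel centers.
place_disks_inside <- function(parent_cy, parent_cx, parent_r, radii, gap,
                               max_tries = 1000L, restarts = 50L,
                               what = "focus") {
  n <- length(radii)
  if (n == 0L) return(data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0)))
  for (attempt in seq_len(restarts)) {
    cy <- cx <- numeric(n)
    ok_all <- TRUE
    for (i in seq_len(n)) {
      rmax <- parent_r - radii[i] - 1
      if (rmax <= 0)
        stop_nq("placement_infeasible",
                sprintf("%s radius %.1f does not fit inside parent radius %.1f",
                        what, radii[i], parent_r))
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        a <- stats::runif(1, 0, 2 * pi)
        d <- rmax * sqrt(stats::runif(1))
        yy <- parent_cy + d * sin(a); xx <- parent_cx + d * cos(a)
        if (i == 1L) placed <- TRUE
        else {
          j <- seq_len(i - 1L)
          placed <- all((yy - cy[j])^2 + (xx - cx[j])^2 >
                          (radii[i] + radii[j] + gap + 1)^2)
        }
        if (placed) { cy[i] <- yy; cx[i] <- xx; break }
      }
      if (!placed) { ok_all <- FALSE; break }
    }
    if (ok_all) return(data.frame(cy = cy, cx = cx, r = radii))
  }
  stop_nq("placement_infeasible",
          sprintf("could not place %d %s objects inside parent after %d restarts",
                  n, what, restarts))
}

# Placement with bounded shrink-and-retry: when a draw of child radii cannot
# be packed into the parent (crowded nuclei / cells), radii are shrunk 10%
# per round (down to min_radius) before giving up. Mirrors the observation
# that crowded organelles are smaller; keeps truly infeasible specs failing.
place_disks_inside_shrink <- function(parent_cy, parent_cx, parent_r, radii,
                                      gap, what, min_radius = 1.5,
                                      shrink_rounds = 8L) {
  for (round in seq_len(shrink_rounds)) {
    res <- tryCatch(
      place_disks_inside(parent_cy, parent_cx, parent_r, radii, gap, what = what),
      nucleoquant_placement_infeasible = function(e) NULL)
    if (!is.null(res)) return(res)
    radii <- pmax(min_radius, radii * 0.9)
  }
  place_disks_inside(parent_cy, parent_cx, parent_r, radii, gap, what = what)
}

add_noise <- function(mat, sd) {
  if (sd <= 0) return(mat)
  pmax(0, mat + matrix(stats::rnorm(length(mat), 0, sd), nrow(mat), ncol(mat)))
}

#' Generate a ground-truthed nucleolar scene
#'
#' Renders a two-channel micrograph (`dna`, `marker`) and returns, with it,
#' the exact per-nucleus ground truth and the noiseless label renderings so
#' downstream segmentation and morphometry can be checked pixel for pixel.
#'
#' @param spec a [nucleolar_scene_spec].
#' @return a list with elements `image` ([multichannel_image]), `truth`
#'   (data.frame: `nucleus_id`, `nucleolus_count`, `nucleolar_area_px`,
#'   `nuclear_area_px`, `enrichment`), `nuclei` and `nucleoli`
#'   ([label_mask]s of the noiseless rendering).
#' @export
gen_nucleolar_scene <- function(spec) {
  stopifnot(inherits(spec, "nucleolar_scene_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  with_seed(spec$seed, {
    nuc_lab <- matrix(0L, h, w)
    nlo_lab <- matrix(0L, h, w)
    parent <- integer(0)
    truth <- data.frame(nucleus_id = integer(0), nucleolus_count = integer(0),
                        nucleolar_area_px = integer(0), nuclear_area_px = integer(0),
                        enrichment = numeric(0))
    if (spec$n_nuclei > 0) {
      radii <- pmax(3, stats::rnorm(spec$n_nuclei, spec$nucleus_radius_px[1],
                                    spec$nucleus_radius_px[2]))
      nuclei <- place_disks(h, w, radii, gap = 2, border = 2, what = "nucleus")
      counts <- sample(0:6, spec$n_nuclei, replace = TRUE,
                       prob = spec$nucleoli_per_nucleus)
      next_nlo <- 1L
      for (i in seq_len(spec$n_nuclei)) {
        nuc_lab <- stamp_disk(nuc_lab, nuclei$cy[i], nuclei$cx[i], nuclei$r[i], i)
        k <- counts[i]
        if (k > 0) {
          rr <- pmax(1.5, stats::rnorm(k, spec$nucleolus_radius_px[1],
                                       spec$nucleolus_radius_px[2]))
          pos <- place_disks_inside_shrink(nuclei$cy[i], nuclei$cx[i],
                                           nuclei$r[i], rr,
                                           gap = spec$nucleolus_gap_px,
                                           what = "nucleolus")
          for (j in seq_len(k)) {
            nlo_lab <- stamp_disk(nlo_lab, pos$cy[j], pos$cx[j], pos$r[j], next_nlo)
            parent[as.character(next_nlo)] <- i
            next_nlo <- next_nlo + 1L
          }
        }
      }
      # relabel nuclei and nucleoli 1..N in raster order (the numbering the
      # segmentation functions use) so truth rows align with segmented labels
      # on scenes where recovery is exact
      remap <- relabel_map(nuc_lab)
      nuc_lab <- apply_relabel(nuc_lab, remap)
      counts <- counts[order(remap)]
      parent <- stats::setNames(remap[parent], names(parent))
      nlo_remap <- relabel_map(nlo_lab)
      nlo_lab <- apply_relabel(nlo_lab, nlo_remap)
      if (length(parent))
        parent <- stats::setNames(
          as.integer(parent),
          nlo_remap[as.integer(names(parent))])[order(nlo_remap)]
      nlo_area <- vapply(seq_len(spec$n_nuclei), function(i) {
        kids <- as.integer(names(parent)[parent == i])
        sum(nlo_lab %in% kids)
      }, numeric(1))
      truth <- data.frame(
        nucleus_id = seq_len(spec$n_nuclei),
        nucleolus_count = counts,
        nucleolar_area_px = as.integer(nlo_area),
        nuclear_area_px = as.integer(tabulate(nuc_lab[nuc_lab > 0], spec$n_nuclei)),
        enrichment = spec$nucleolar_enrichment
      )
    }
    marker <- matrix(spec$background_intensity, h, w)
    marker[nuc_lab > 0] <- spec$nucleoplasm_intensity
    marker[nlo_lab > 0] <- spec$nucleoplasm_intensity * spec$nucleolar_enrichment
    dna <- matrix(spec$background_intensity, h, w)
    dna[nuc_lab > 0] <- spec$background_intensity + spec$dna_intensity
    dna <- add_noise(dna, spec$noise_sd)
    marker <- add_noise(marker, spec$noise_sd)
    img <- multichannel_image(array(c(dna, marker), c(h, w, 2L)),
                              c("dna", "marker"))
    list(image = img, truth = truth,
         nuclei = label_mask(nuc_lab),
         nucleoli = label_mask(nlo_lab, parent_map = if (length(parent)) parent else NULL))
  })
}

#' Specification of a synthetic polyQ-EGFP aggregation scene
#'
#' Defaults emulate transfected cells expressing a polyQ-EGFP fusion: each
#' cell carries the same total EGFP signal, distributed either diffusely
#' (0 foci) or concentrated into bright foci (aggregates) at a fixed share
#' of the total. Total signal per cell is conserved regardless of foci
#' count, mirroring equal expression with different aggregation states.
#'
#' @param foci_count_per_cell integer vector, one entry per cell; its length
#'   sets the number of cells.
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param cell_radius_px length-2 `c(mean, sd)` of cell radii.
#' @param nucleus_radius_px nuclear radius (concentric with the cell).
#' @param total_signal_per_cell summed EGFP intensity per cell (conserved).
#' @param focus_radius_px radius of each aggregate focus.
#' @param focus_intensity_share fraction of the cell's total signal placed
#'   in foci (when the cell has any), in `[0, 1]`.
#' @param focus_gap_px minimum boundary gap between foci.
#' @param dna_intensity DNA-channel intensity inside nuclei.
#' @param background_intensity intensity outside all objects.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return a list of class `aggregation_scene_spec`.
#' @export
aggregation_scene_spec <- function(foci_count_per_cell = c(0L, 1L, 3L, 6L, 8L),
                                   image_height_px = 512L, image_width_px = 512L,
                                   cell_radius_px = c(mean = 26, sd = 1.5),
                                   nucleus_radius_px = 8,
                                   total_signal_per_cell = 20000,
                                   focus_radius_px = 3,
                                   focus_intensity_share = 0.5,
                                   focus_gap_px = 4,
                                   dna_intensity = 80,
                                   background_intensity = 2,
                                   noise_sd = 0.2,
                                   seed = 1L) {
  if (focus_intensity_share > 1 || focus_intensity_share < 0)
    stop_nq("invalid_spec", "focus_intensity_share must lie in [0, 1]")
  if (any(foci_count_per_cell < 0))
    stop_nq("invalid_spec", "foci counts must be non-negative")
  if (total_signal_per_cell <= 0)
    stop_nq("invalid_spec", "total_signal_per_cell must be positive")
  n_cells <- length(foci_count_per_cell)
  structure(c(as.list(environment())), class = "aggregation_scene_spec")
}

#' Map a focus count to an aggregation score
#'
#' The scoring rule for polyQ aggregation state: `S0` for cells without
#' aggregates, `S1` for 1-5 aggregates, `S2` for more than 5.
#'
#' @param foci_count integer vector of per-cell aggregate counts.
#' @return character vector of scores (`"S0"`, `"S1"`, `"S2"`).
#' @export
score_from_count <- function(foci_count) {
  ifelse(foci_count == 0, "S0", ifelse(foci_count <= 5, "S1", "S2"))
}

#' Generate a ground-truthed aggregation scene
#'
#' Renders a two-channel micrograph (`dna`, `egfp`). Each cell's noiseless
#' integrated EGFP signal equals `total_signal_per_cell` exactly; cells with
#' foci concentrate `focus_intensity_share` of it into equal-intensity
#' disks, the rest spread uniformly over the cell.
#'
#' @param spec an [aggregation_scene_spec].
#' @return a list with `image` ([multichannel_image]), `truth` (data.frame:
#'   `cell_id`, `foci_count`, `expected_score`, `egfp_total`), `cells`,
#'   `nuclei` ([label_mask]s) and `foci` (data.frame of focus geometry).
#' @export
gen_aggregation_scene <- function(spec) {
  stopifnot(inherits(spec, "aggregation_scene_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  n <- spec$n_cells
  with_seed(spec$seed, {
    cell_lab <- matrix(0L, h, w)
    nuc_lab <- matrix(0L, h, w)
    egfp <- matrix(spec$background_intensity, h, w)
    foci_tbl <- data.frame(cell_id = integer(0), cy = numeric(0),
                           cx = numeric(0), r = numeric(0))
    if (n > 0) {
      radii <- pmax(spec$nucleus_radius_px + 2,
                    stats::rnorm(n, spec$cell_radius_px[1], spec$cell_radius_px[2]))
      cells <- place_disks(h, w, radii, gap = 3, border = 2, what = "cell")
      for (i in seq_len(n)) {
        cell_lab <- stamp_disk(cell_lab, cells$cy[i], cells$cx[i], cells$r[i], i)
        nuc_lab <- stamp_disk(nuc_lab, cells$cy[i], cells$cx[i],
                              spec$nucleus_radius_px, i)
      }
      # renumber cells (and their concentric nuclei) in raster order so truth
      # rows align with segmentation labels
      remap <- relabel_map(cell_lab)
      cell_lab <- apply_relabel(cell_lab, remap)
      nuc_lab <- apply_relabel(nuc_lab, remap)
      cells <- cells[order(remap), , drop = FALSE]
      spec$foci_count_per_cell <- spec$foci_count_per_cell[order(remap)]
      for (i in seq_len(n)) {
        cell_px <- which(cell_lab == i)
        k <- spec$foci_count_per_cell[i]
        share <- if (k > 0) spec$focus_intensity_share else 0
        egfp[cell_px] <- egfp[cell_px] +
          spec$total_signal_per_cell * (1 - share) / length(cell_px)
        if (k > 0) {
          pos <- place_disks_inside_shrink(cells$cy[i], cells$cx[i], cells$r[i],
                                           rep(spec$focus_radius_px, k),
                                           gap = spec$focus_gap_px,
                                           what = "focus", min_radius = 2)
          for (j in seq_len(k)) {
            fmask <- matrix(0L, h, w)
            fmask <- stamp_disk(fmask, pos$cy[j], pos$cx[j], pos$r[j], 1L)
            fpx <- which(fmask > 0 & cell_lab == i)
            egfp[fpx] <- egfp[fpx] +
              spec$total_signal_per_cell * share / k / length(fpx)
          }
          foci_tbl <- rbind(foci_tbl,
                            data.frame(cell_id = i, cy = pos$cy, cx = pos$cx,
                                       r = pos$r))
        }
      }
    }
    egfp_total <- if (n > 0)
      vapply(seq_len(n), function(i)
        sum(egfp[cell_lab == i]) - spec$background_intensity * sum(cell_lab == i),
        numeric(1))
    else numeric(0)
    truth <- data.frame(
      cell_id = seq_len(n),
      foci_count = as.integer(spec$foci_count_per_cell),
      expected_score = score_from_count(spec$foci_count_per_cell),
      egfp_total = egfp_total
    )
    dna <- matrix(spec$background_intensity, h, w)
    dna[nuc_lab > 0] <- spec$background_intensity + spec$dna_intensity
    dna <- add_noise(dna, spec$noise_sd)
    egfp <- add_noise(egfp, spec$noise_sd)
    img <- multichannel_image(array(c(dna, egfp), c(h, w, 2L)), c("dna", "egfp"))
    list(image = img, truth = truth,
         cells = label_mask(cell_lab), nuclei = label_mask(nuc_lab),
         foci = foci_tbl)
  })
}
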