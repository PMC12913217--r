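# Nucleolar morphometry: segmentation rules, merging, masking, per-nucleus
# statistics and their invariances.

test_that("noiseless disks are segmented with areas matching truth within 2%", {
  spec <- nucleolar_scene_spec(n_nuclei = 5L, noise_sd = 0, seed = 7L)
  sc <- gen_nucleolar_scene(spec)
  nuc <- segment_nuclei(sc$image)
  expect_identical(n_objects(nuc), 5L)
  m <- map_to_truth(nuc$labels, sc$nuclei$labels)
  expect_false(anyNA(m))
  for (i in seq_len(5)) {
    seg_area <- sum(nuc$labels == m[i])
    expect_equal(seg_area, sc$truth$nuclear_area_px[i],
                 tolerance = 0.02)
  }
})

test_that("blank images yield no nuclei", {
  img <- img2(matrix(3, 64, 64), matrix(3, 64, 64))
  expect_identical(n_objects(segment_nuclei(img)), 0L)
})

test_that("border-touching nuclei are excluded unless asked otherwise", {
  dna <- matrix(0, 64, 64)
  dna[one_disk(64, 64, 5, 32, 8) > 0] <- 100   # clipped by the top border
  dna[one_disk(64, 64, 40, 32, 8) > 0] <- 100  # interior
  img <- img2(dna, dna * 0)
  expect_identical(n_objects(segment_nuclei(img, exclude_border = TRUE)), 1L)
  expect_identical(n_objects(segment_nuclei(img, exclude_border = FALSE)), 2L)
})

test_that("unknown channels raise ChannelNotFound", {
  img <- img2(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_error(segment_nuclei(img, dna_channel = "hoechst"),
               class = "nucleoquant_channel_not_found")
})

test_that("adjacent nucleolus fragments merge by boundary gap", {
  # one nucleus, two bright 3x4 blobs separated by a 1-px gap
  nuc <- matrix(0L, 40, 40); nuc[8:32, 8:32] <- 1L
  marker <- matrix(5, 40, 40)
  marker[nuc > 0] <- 40
  marker[15:18, 14:16] <- 120
  marker[15:18, 18:20] <- 120  # gap of 1 px (column 17)
  img <- img2(matrix(0, 40, 40), marker)
  merged <- segment_nucleoli(img, "marker", label_mask(nuc), merge_distance_px = 2L)
  expect_identical(n_objects(merged), 1L)
  split <- segment_nucleoli(img, "marker", label_mask(nuc), merge_distance_px = 0L)
  expect_identical(n_objects(split), 2L)
  # a gap wider than merge_distance_px stays split
  marker2 <- matrix(5, 40, 40); marker2[nuc > 0] <- 40
  marker2[15:18, 12:14] <- 120
  marker2[15:18, 18:20] <- 120  # gap of 3 px
  far <- segment_nucleoli(img2(matrix(0, 40, 40), marker2), "marker",
                          label_mask(nuc), merge_distance_px = 2L)
  expect_identical(n_objects(far), 2L)
})

test_that("marker signal outside nuclei is masked away", {
  nuc <- matrix(0L, 40, 40); nuc[5:18, 5:18] <- 1L
  marker <- matrix(5, 40, 40)
  marker[nuc > 0] <- 40
  marker[28:33, 28:33] <- 200  # bright blob fully outside the nucleus
  img <- img2(matrix(0, 40, 40), marker)
  nlo <- segment_nucleoli(img, "marker", label_mask(nuc))
  expect_identical(n_objects(nlo), 0L)
})

test_that("a nucleus without nucleolar signal keeps zero children but is measured", {
  nuc <- matrix(0L, 30, 30); nuc[5:25, 5:25] <- 1L
  marker <- matrix(2, 30, 30); marker[nuc > 0] <- 40  # flat inside
  img <- img2(matrix(0, 30, 30), marker)
  nlo <- segment_nucleoli(img, "marker", label_mask(nuc))
  expect_identical(n_objects(nlo), 0L)
  m <- measure_nuclei(img, "marker", label_mask(nuc), nlo)
  expect_identical(nrow(m), 1L)
  expect_identical(m$nucleolus_count, 0L)
  expect_true(is.na(m$presence_ratio))
})

test_that("presence ratio, size fold and integrated intensity follow their definitions", {
  nuc <- matrix(0L, 30, 40); nuc[3:22, 3:27] <- 1L       # 20 x 25 = 500 px
  nlo <- matrix(0L, 30, 40); nlo[5:9, 5:14] <- 1L        # 5 x 10 = 50 px
  v <- 12
  marker <- matrix(0, 30, 40)
  marker[nuc > 0] <- v
  marker[nlo > 0] <- 2 * v
  img <- img2(matrix(0, 30, 40), marker)
  m <- measure_nuclei(img, "marker", label_mask(nuc),
                      label_mask(nlo, parent_map = c(`1` = 1L)))
  expect_equal(m$presence_ratio, 2.0)
  expect_equal(m$size_fold, 0.1)
  expect_equal(m$marker_nucleolar_integrated, 50 * 2 * v)
  # uniform marker -> presence ratio exactly 1
  marker1 <- matrix(0, 30, 40); marker1[nuc > 0] <- v
  m1 <- measure_nuclei(img2(matrix(0, 30, 40), marker1), "marker",
                       label_mask(nuc), label_mask(nlo, parent_map = c(`1` = 1L)))
  expect_equal(m1$presence_ratio, 1.0)
})

test_that("nucleolar and nucleoplasmic pixels partition each nucleus exactly", {
  sc <- gen_nucleolar_scene(nucleolar_scene_spec(n_nuclei = 6L, seed = 13L))
  nuc <- segment_nuclei(sc$image)
  nlo <- segment_nucleoli(sc$image, "marker", nuc)
  pm <- nlo$parent_map
  for (i in sort(unique(nuc$labels[nuc$labels > 0]))) {
    nuc_px <- which(nuc$labels == i)
    kids <- if (is.null(pm)) integer(0) else as.integer(names(pm)[pm == i])
    nlo_px <- which(nuc$labels == i & nlo$labels %in% kids & nlo$labels > 0)
    plasm_px <- which(nuc$labels == i & !(nlo$labels %in% kids & nlo$labels > 0))
    expect_identical(sort(c(nlo_px, plasm_px)), nuc_px)
    expect_length(intersect(nlo_px, plasm_px), 0)
  }
})

test_that("ratios are invariant to intensity scaling; integrated scales linearly", {
  sc <- gen_nucleolar_scene(nucleolar_scene_spec(n_nuclei = 4L, seed = 3L))
  nuc <- segment_nuclei(sc$image)
  nlo <- segment_nucleoli(sc$image, "marker", nuc)
  m1 <- measure_nuclei(sc$image, "marker", nuc, nlo)
  a <- 3.7
  px <- sc$image$pixels
  px[, , 2] <- px[, , 2] * a
  scaled <- multichannel_image(px, sc$image$channel_names)
  m2 <- measure_nuclei(scaled, "marker", nuc, nlo)
  expect_equal(m2$presence_ratio, m1$presence_ratio)
  expect_equal(m2$size_fold, m1$size_fold)
  expect_equal(m2$marker_nucleolar_integrated, a * m1$marker_nucleolar_integrated)
})

test_that("nascent-RNA measurements read the FUrd channel over nucleolar pixels", {
  sc <- gen_nucleolar_scene(nucleolar_scene_spec(n_nuclei = 3L, seed = 17L))
  nuc <- segment_nuclei(sc$image)
  nlo <- segment_nucleoli(sc$image, "marker", nuc)
  # furd == marker -> identical integrated intensity
  px <- sc$image$pixels
  furd_img <- multichannel_image(array(c(px[, , 1], px[, , 2], px[, , 2]),
                                       c(dim(px)[1:2], 3L)),
                                 c("dna", "marker", "furd"))
  mm <- measure_nuclei(furd_img, "marker", nuc, nlo)
  fr <- measure_nascent_rna(furd_img, "furd", nuc, nlo)
  expect_equal(fr$furd_nucleolar_integrated, mm$marker_nucleolar_integrated)
  # all-zero furd channel -> zero integrated signal
  px0 <- furd_img$pixels; px0[, , 3] <- 0
  fr0 <- measure_nascent_rna(multichannel_image(px0, furd_img$channel_names),
                             "furd", nuc, nlo)
  expect_true(all(fr0$furd_nucleolar_integrated == 0))
  # doubling doubles integrated, preserves median order
  px2 <- furd_img$pixels; px2[, , 3] <- 2 * px2[, , 3]
  fr2 <- measure_nascent_rna(multichannel_image(px2, furd_img$channel_names),
                             "furd", nuc, nlo)
  expect_equal(fr2$furd_nucleolar_integrated, 2 * fr$furd_nucleolar_integrated)
  expect_identical(order(fr2$furd_nucleolar_median), order(fr$furd_nucleolar_median))
})

test_that("qc overlay has image dimensions and outlines every nucleus once", {
  sc <- gen_nucleolar_scene(nucleolar_scene_spec(n_nuclei = 5L, seed = 23L))
  nuc <- segment_nuclei(sc$image)
  nlo <- segment_nucleoli(sc$image, "marker", nuc)
  ov <- qc_overlay(sc$image, nuc, nlo)
  expect_identical(dim(ov), c(dim(sc$image$pixels)[1:2], 3L))
  # every one of the 5 nuclei contributes a yellow outline
  yellow <- ov[, , 1] == 1 & ov[, , 2] == 1 & ov[, , 3] == 0
  for (i in 1:5) {
    ring <- nuc$labels == i & !(nuc$labels %in% 0)  # nucleus i pixels
    expect_gt(sum(yellow & ring), 0)
  }
  expect_identical(length(unique(nuc$labels[yellow])), 5L)
  # empty masks leave the composite unmodified
  empty <- label_mask(matrix(0L, dim(ov)[1], dim(ov)[2]))
  ov0 <- qc_overlay(sc$image, empty, empty)
  base <- apply(sc$image$pixels, c(1, 2), mean)
  base <- (base - min(base)) / diff(range(base))
  expect_equal(ov0[, , 1], base)
})

test_that("misaligned masks raise MaskMismatch", {
  sc <- gen_nucleolar_scene(nucleolar_scene_spec(n_nuclei = 2L, seed = 2L,
                                                 image_height_px = 128L,
                                                 image_width_px = 128L))
  bad <- label_mask(matrix(0L, 64, 64))
  expect_error(measure_nuclei(sc$image, "marker", bad, bad),
               class = "nucleoquant_mask_mismatch")
})
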