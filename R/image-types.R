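# Core containers: multi-channel images and aligned label masks, plus
# TIFF I/O with JSON ground-truth sidecars.

#' Construct a multi-channel image
#'
#' A thin container around an `H x W x C` array of non-negative intensities
#' with unique channel names. Rows index the vertical (y) axis, columns the
#' horizontal (x) axis; coordinates used elsewhere in the package are
#' therefore `(row, col)`, 1-based.
#'
#' @param pixels numeric `H x W` matrix (single channel) or `H x W x C` array.
#' @param channel_names character vector of length C, unique.
#' @param pixel_size_um optional physical pixel size in micrometres.
#' @return an object of class `multichannel_image`.
#' @examples
#' img <- multichannel_image(array(0, c(8, 8, 2)), c("dna", "marker"))
#' dim(channel(img, "dna"))
#' @export
multichannel_image <- function(pixels, channel_names, pixel_size_um = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (any(pixels < 0)) stop_nq("invalid_image", "intensities must be non-negative")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(pixels)[3])
    stop_nq("invalid_image", "channel_names length must equal the number of channels")
  if (anyDuplicated(channel_names))
    stop_nq("invalid_image", "channel names must be unique")
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0))
    stop_nq("invalid_image", "pixel_size_um must be a positive number")
  structure(
    list(pixels = pixels, channel_names = channel_names,
         pixel_size_um = pixel_size_um),
    class = "multichannel_image"
  )
}

#' Extract one channel as an H x W matrix
#'
#' @param image a [multichannel_image].
#' @param name channel name.
#' @return numeric matrix.
#' @export
channel <- function(image, name) {
  stopifnot(inherits(image, "multichannel_image"))
  i <- match(name, image$channel_names)
  if (is.na(i))
    stop_nq("channel_not_found",
            sprintf("channel '%s' not found (available: %s)", name,
                    paste(image$channel_names, collapse = ", ")))
  image$pixels[, , i]
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multichannel_image> %d x %d px, channels: %s\n",
              d[1], d[2], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Construct a label mask
#'
#' Integer object labels aligned to an image: 0 is background, `k > 0` is
#' object `k`. An optional `parent_map` links child objects (e.g. nucleoli)
#' to parent labels in another mask (e.g. nuclei); it is a named integer
#' vector, names being child labels.
#'
#' @param labels integer `H x W` matrix.
#' @param parent_map optional named integer vector mapping child label ->
#'   parent label.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, parent_map = NULL) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop_nq("invalid_mask", "labels must be >= 0")
  if (!is.null(parent_map)) {
    parent_map <- stats::setNames(as.integer(parent_map), names(parent_map))
    ids <- sort(unique(labels[labels > 0]))
    if (!all(as.character(ids) %in% names(parent_map)))
      stop_nq("invalid_mask", "every child label needs exactly one parent in parent_map")
  }
  structure(list(labels = labels, parent_map = parent_map), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d object(s)%s\n",
              nrow(x$labels), ncol(x$labels), n_objects(x),
              if (is.null(x$parent_map)) "" else " (with parent_map)"))
  invisible(x)
}

#' Number of labeled objects in a mask
#' @param mask a [label_mask].
#' @export
n_objects <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  length(unique(mask$labels[mask$labels > 0]))
}

check_aligned <- function(image, mask) {
  d <- dim(image$pixels)[1:2]
  if (!identical(as.integer(d), as.integer(dim(mask$labels))))
    stop_nq("mask_mismatch",
            sprintf("mask is %d x %d but image is %d x %d",
                    nrow(mask$labels), ncol(mask$labels), d[1], d[2]))
  invisible(TRUE)
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' One page per channel, 32-bit float, with channel names recorded in a JSON
#' sidecar (`<path>.json`) alongside any ground truth supplied.
#'
#' @param image a [multichannel_image].
#' @param path output TIFF path.
#' @param truth optional list/data.frame of ground truth for the sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, truth = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  # float TIFF storage is defined on [0, 1]; rescale per channel and record
  # the factor in the sidecar
  scales <- vapply(seq_along(image$channel_names),
                   function(i) max(image$pixels[, , i], 1), numeric(1))
  pages <- lapply(seq_along(image$channel_names),
                  function(i) image$pixels[, , i] / scales[i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(channel_names = image$channel_names,
               channel_scales = scales,
               pixel_size_um = image$pixel_size_um)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF as a multi-channel image
#'
#' Channel names come from the JSON sidecar when present, from
#' `channel_names` otherwise, defaulting to `ch1..chC`.
#'
#' @param path TIFF path.
#' @param channel_names optional channel names overriding the sidecar.
#' @return a [multichannel_image].
#' @export
read_image <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  side_path <- paste0(path, ".json")
  meta <- if (file.exists(side_path)) jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  if (!is.null(meta$channel_scales))
    pages <- Map(`*`, pages, as.numeric(meta$channel_scales))
  px <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  if (is.null(channel_names))
    channel_names <- meta$channel_names %||% paste0("ch", seq_len(length(pages)))
  multichannel_image(px, channel_names, pixel_size_um = meta$pixel_size_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
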