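# Shared fixture builders and oracle helpers. All fixtures are generated in
# code; nothing is read from disk.

# For each truth object id, the segmented label covering most of its pixels
# (NA when no segmented pixel overlaps it).
map_to_truth <- function(seg_labels, truth_labels) {
  ids <- sort(unique(truth_labels[truth_labels > 0]))
  vapply(ids, function(i) {
    s <- seg_labels[truth_labels == i]
    s <- s[s > 0]
    if (!length(s)) NA_integer_ else as.integer(names(which.max(table(s))))
  }, integer(1))
}

# two-channel image from plain matrices
img2 <- function(dna, marker, names = c("dna", "marker")) {
  multichannel_image(array(c(dna, marker), c(dim(dna), 2L)), names)
}

# a single centered disk mask as a label matrix
one_disk <- function(h, w, cy, cx, r, value = 1L) {
  m <- matrix(0L, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- value
  m
}

# analytic Gaussian mixture used by the dense-grid valley oracle
mixture_fun <- function(peaks, baseline) {
  function(x) {
    y <- rep(baseline, length(x))
    for (i in seq_len(nrow(peaks)))
      y <- y + peaks$area[i] * stats::dnorm(x, peaks$center[i], peaks$width[i])
    y
  }
}
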