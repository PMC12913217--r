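# Polysome-profile quantification: parsing, valley anchoring against a
# dense-grid oracle, normalization, window sums and their invariances.

test_that("traces load from TSV and CSV dialects identically", {
  g <- gen_polysome_trace(trace_spec(n_samples = 200L, seed = 1L))
  tsv <- tempfile(fileext = ".tsv"); csv <- tempfile(fileext = ".csv")
  write_trace(g$trace, tsv)
  write.csv(data.frame(position = g$trace$x, od260 = g$trace$y), csv,
            row.names = FALSE)
  t1 <- load_trace(tsv)
  t2 <- load_trace(csv)
  expect_length(t1$x, 200L)
  expect_equal(t1$x, t2$x)
  expect_equal(t1$y, t2$y)
  unlink(c(tsv, csv))
})

test_that("duplicated x values raise NonMonotonicX", {
  f <- tempfile()
  writeLines(c("x\ty", paste(c(1:30, 30, 31:60), runif(62), sep = "\t")), f)
  expect_error(load_trace(f), class = "nucleoquant_non_monotonic_x")
  unlink(f)
})

test_that("non-uniform spacing warns, resamples on request, and blocks sum integration", {
  x <- sort(c(seq(0, 100, length.out = 190), runif(10, 1, 99)))
  y <- dnorm(x, 50, 10)
  f <- tempfile()
  write.table(data.frame(x, y), f, sep = "\t", row.names = FALSE)
  expect_warning(tr <- load_trace(f), "non-uniform")
  expect_false(tr$uniform_spacing)
  rs <- load_trace(f, resample = TRUE)
  expect_true(rs$uniform_spacing)
  unlink(f)
})

test_that("anchors land within one sample of the dense-grid argmin oracle", {
  pk <- data.frame(label = c("40S", "60S", "80S", "disome"),
                   center = c(10, 20, 32, 45), width = 2, area = c(6, 10, 30, 12))
  spec <- trace_spec(pk, baseline = 0.02, noise_sd = 0, n_samples = 500L,
                     x_range = c(0, 60))
  g <- gen_polysome_trace(spec)
  anchors <- find_anchor_valleys(g$trace)
  mix <- mixture_fun(pk, 0.02)
  dx <- diff(g$trace$x[1:2])
  grid1 <- seq(20, 32, length.out = 100001)
  grid2 <- seq(32, 45, length.out = 100001)
  expect_lt(abs(g$trace$x[anchors$anchor_start_idx] - grid1[which.min(mix(grid1))]),
            dx + 1e-9)
  expect_lt(abs(g$trace$x[anchors$anchor_mono_di_idx] - grid2[which.min(mix(grid2))]),
            dx + 1e-9)
})

test_that("monotone traces and flat plateaus are handled as specified", {
  expect_error(find_anchor_valleys(polysome_trace(1:60, seq(1, 10, length.out = 60))),
               class = "nucleoquant_too_few_peaks")
  # flat-bottomed valley: the leftmost plateau index is chosen
  y <- rep(0.2, 100)
  y[15:25] <- 0.2 + dnorm(15:25, 20, 2)          # 60S
  y[40:60] <- 0.2 + 3 * dnorm(40:60, 50, 3)      # 80S (tallest)
  y[70:80] <- 0.2 + dnorm(70:80, 75, 2)          # disome
  # plateau between 60S and 80S at exactly 0.2 spans indices 26..39
  a <- find_anchor_valleys(polysome_trace(1:100, y), smoothing_window = 1L)
  expect_identical(a$anchor_start_idx, 26L)
})

test_that("normalization maps min/max to 0/1 and anchors X as specified", {
  g <- gen_polysome_trace(trace_spec(seed = 5L))
  anchors <- find_anchor_valleys(g$trace)
  nm <- normalize_trace(g$trace, anchors)
  expect_equal(min(nm$y_norm), 0)
  expect_equal(max(nm$y_norm), 1)
  expect_equal(nm$x_norm[nm$anchor_start_idx], 0)
  expect_equal(nm$x_norm[length(nm$x_norm)], 100)
  # y -> 2y + 0.3 leaves y_norm identical to machine precision
  t2 <- polysome_trace(g$trace$x, 2 * g$trace$y + 0.3)
  nm2 <- normalize_trace(t2, find_anchor_valleys(t2))
  expect_equal(nm2$y_norm, nm$y_norm, tolerance = 1e-12)
  # constant trace is degenerate
  expect_error(normalize_trace(polysome_trace(1:60, rep(1, 60)), anchors),
               class = "nucleoquant_degenerate_trace")
})

test_that("fraction windows follow the boundary rule and zero tails give ratio 0", {
  # trace whose y equals its minimum everywhere past the mono/di anchor
  y <- rep(0, 200)
  y[30:70] <- dnorm(30:70, 50, 5)
  tr <- polysome_trace(seq_len(200), y + 0.0)
  anchors <- list(anchor_start_idx = 20L, anchor_mono_di_idx = 90L,
                  smoothing_window = 1L)
  q <- integrate_fractions(normalize_trace(tr, anchors))
  expect_identical(q$polysome_fraction, 0)
  expect_identical(q$pm_ratio, 0)
  # boundary sample is counted once, in the monosome window by default
  nm <- normalize_trace(tr, anchors)
  q_m <- integrate_fractions(nm, boundary = "monosome")
  q_p <- integrate_fractions(nm, boundary = "polysome")
  expect_equal(q_m$monosome_fraction - nm$y_norm[90], q_p$monosome_fraction)
  expect_equal(q_m$monosome_fraction + q_m$polysome_fraction,
               q_p$monosome_fraction + q_p$polysome_fraction)
})

test_that("constructed 2:1 profiles recover the ratio within 10%", {
  g <- gen_polysome_trace(trace_spec(peaks_with_ratio(2), baseline = 0.02,
                                     noise_sd = 0))
  q <- quantify_polysome(g$trace)
  expect_equal(q$pm_ratio, 2.0, tolerance = 0.1)
})

test_that("doubling the sampling density changes the ratio by under 1%", {
  q1 <- quantify_polysome(gen_polysome_trace(
    trace_spec(noise_sd = 0, n_samples = 600L))$trace)
  q2 <- quantify_polysome(gen_polysome_trace(
    trace_spec(noise_sd = 0, n_samples = 1200L))$trace)
  expect_lt(abs(q2$pm_ratio - q1$pm_ratio) / q1$pm_ratio, 0.01)
})

test_that("the ratio is invariant to affine transforms of both axes", {
  g <- gen_polysome_trace(trace_spec(seed = 9L))
  q0 <- quantify_polysome(g$trace)
  qy <- quantify_polysome(polysome_trace(g$trace$x, 2 * g$trace$y + 0.3))
  qx <- quantify_polysome(polysome_trace(3 * g$trace$x - 5, g$trace$y))
  expect_lt(abs(qy$pm_ratio - q0$pm_ratio), 1e-9)
  expect_lt(abs(qx$pm_ratio - q0$pm_ratio), 1e-9)
})

test_that("sum-based fractions agree with trapezoid integrals within 2%", {
  for (s in 1:5) {
    g <- gen_polysome_trace(trace_spec(seed = s))
    nm <- normalize_trace(g$trace, find_anchor_valleys(g$trace))
    qs <- integrate_fractions(nm, method = "sum")
    qt <- integrate_fractions(nm, method = "trapezoid")
    dx <- diff(nm$x_norm[1:2])
    expect_equal(qs$monosome_fraction * dx, qt$monosome_fraction, tolerance = 0.02)
    expect_equal(qs$polysome_fraction * dx, qt$polysome_fraction, tolerance = 0.02)
  }
})

test_that("profile comparison tabulates per-condition means and sds", {
  df <- data.frame(sample = c("a", "b", "c"),
                   condition = c("wt", "ko", "ko"),
                   pm_ratio = c(1.5, 0.8, 0.8))
  res <- compare_profiles(df)
  expect_identical(res$summary$condition, c("wt", "ko"))
  expect_equal(res$summary$mean, c(1.5, 0.8))
  expect_equal(res$summary$sd, c(0, 0))
  # permuting rows leaves the per-condition summaries unchanged
  res2 <- compare_profiles(df[c(3, 1, 2), ])
  s1 <- res$summary[order(res$summary$condition), ]
  s2 <- res2$summary[order(res2$summary$condition), ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})
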