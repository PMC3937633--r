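test_that("sliding-window smoothing behaves on canonical signals", {
  # constant trace unchanged
  expect_equal(smooth_trace(rep(7, 30)), rep(7, 30))
  # alternating +/-1 shrinks toward 0 in the interior of a 10-point window
  alt <- rep(c(-1, 1), 20)
  sm <- smooth_trace(alt, 10)
  expect_true(all(abs(sm[6:35]) <= 0.2 + 1e-12))
  # linear ramp: interior points are unchanged (mean of a symmetric window
  # of 9 points; the 10th sample adds a constant half-step offset)
  ramp <- seq(0, 100, length.out = 41)
  sm9 <- smooth_trace(ramp, 9)
  expect_equal(sm9[5:37], ramp[5:37])
  # degenerate window warns and returns the global mean
  expect_warning(out <- smooth_trace(1:5, 10), "window")
  expect_equal(out, rep(3, 5))
})

test_that("response threshold is the midpoint of the range and scales linearly", {
  v <- c(100, 150, 300, 220)
  expect_equal(response_threshold(v), 200)
  expect_equal(response_threshold(3.5 * v), 3.5 * 200)
  tr <- hif_simulate(med, protocol_deoxygenation())
  expect_equal(response_threshold(tr$x), (max(tr$x) + min(tr$x)) / 2)
})

test_that("excursion crossing times are interpolated below the sampling step", {
  t <- seq(0, 1000, by = 5)
  # square pulse above threshold on [100, 300)
  sq <- ifelse(t >= 100 & t < 300, 10, 0)
  exc <- trace_excursions(t, sq, 5)
  expect_equal(nrow(exc), 1)
  expect_equal(exc$duration, 200, tolerance = 0.03)
  # two pulses are reported in time order
  sq2 <- sq + ifelse(t >= 600 & t < 700, 10, 0)
  exc2 <- trace_excursions(t, sq2, 5)
  expect_equal(nrow(exc2), 2)
  expect_true(exc2$t_up[1] < exc2$t_up[2])
  # triangular pulse: closed-form crossings at 50 and 150 for threshold 1/2
  tri <- linear_pulse(t, t_on = 0, t_peak = 100, t_off = 200,
                      base = 0, amp = 1)
  exc3 <- trace_excursions(t, tri, 0.5)
  expect_equal(exc3$t_up, 50, tolerance = 1e-9)
  expect_equal(exc3$t_down, 150, tolerance = 1e-9)
  expect_equal(exc3$duration, 100, tolerance = 1e-9)
  # unterminated excursion flagged, duration measured to trace end
  open_p <- ifelse(t >= 800, 10, 0)
  exc4 <- trace_excursions(t, open_p, 5)
  expect_true(exc4$unterminated)
  expect_equal(exc4$t_down, 1000)
})

test_that("response classes follow the 280-min rule and the peak count", {
  t <- seq(0, 1260, by = 5)
  # one 200-min pulse -> transient
  p200 <- linear_pulse(t, 200, 300, 400)
  expect_identical(classify_response(t, p200)$class, "transient")
  # a pulse 300 min above half-maximum -> prolonged
  p400 <- linear_pulse(t, 100, 400, 700)
  r400 <- classify_response(t, p400)
  expect_identical(r400$class, "prolonged")
  expect_gt(r400$durations[1], 280)
  # two pulses, both clearing the noise guard -> multiple
  p2 <- linear_pulse(t, 100, 180, 260) + linear_pulse(t, 500, 580, 660) - 100
  r2 <- classify_response(t, p2)
  expect_identical(r2$class, "multiple")
  expect_identical(r2$n_peaks, 2L)
  # constant trace -> non-responder
  expect_identical(classify_response(t, rep(5, length(t)))$class,
                   "non_responder")
  # pure noise -> non-responder (amplitude floor)
  set.seed(71)
  expect_identical(classify_response(t, rnorm(length(t), 100, 5))$class,
                   "non_responder")
})

test_that("classification is invariant under positive affine intensity maps", {
  t <- seq(0, 1260, by = 5)
  fixtures <- list(
    transient = linear_pulse(t, 200, 300, 400),
    prolonged = linear_pulse(t, 100, 400, 700),
    multiple = linear_pulse(t, 100, 180, 260) +
      linear_pulse(t, 500, 580, 660) - 100)
  set.seed(12)
  for (nm in names(fixtures)) {
    v <- fixtures[[nm]] + rnorm(length(t), 0, 2)
    r0 <- classify_response(t, v)
    r1 <- classify_response(t, 3.7 * v + 50)
    expect_identical(r1$class, r0$class)
    expect_identical(r1$n_peaks, r0$n_peaks)
    expect_equal(r1$durations, r0$durations, tolerance = 1e-9)
    expect_equal(r1$threshold, 3.7 * r0$threshold + 50, tolerance = 1e-9)
  }
})

test_that("concatenating disjoint pulses yields the union of their excursions", {
  t1 <- seq(0, 600, by = 5)
  a <- linear_pulse(t1, 100, 200, 300, base = 0, amp = 10)
  t2 <- seq(605, 1200, by = 5)
  b <- linear_pulse(t2, 800, 900, 1000, base = 0, amp = 10)
  thr <- 5
  ea <- trace_excursions(t1, a, thr)
  eb <- trace_excursions(t2, b, thr)
  eab <- trace_excursions(c(t1, t2), c(a, b), thr)
  expect_equal(eab$t_up, c(ea$t_up, eb$t_up), tolerance = 1e-12)
  expect_equal(eab$duration, c(ea$duration, eb$duration), tolerance = 1e-12)
})

test_that("the median-cell pulse is classified by the standard code path", {
  tr <- hif_simulate(med, protocol_deoxygenation(), times = seq(0, 1260, 5))
  r <- classify_response(tr$time, tr$x)
  expect_true(r$class %in% c("transient", "prolonged"))
  expect_identical(r$n_peaks, 1L)
  # duration sits near the 280-min transient boundary
  expect_gt(r$durations[1], 250)
  expect_lt(r$durations[1], 350)
})

test_that("half-life estimation inverts exponential decay", {
  t <- seq(0, 1440, by = 5)
  expect_equal(estimate_half_life(t, exp(-log(2) / 102 * t)), 1.7,
               tolerance = 1e-9)
  expect_equal(estimate_half_life(t, 5 * exp(-log(2) / 720 * t)), 12,
               tolerance = 1e-9)
  # non-decaying trace flagged with infinite half-life
  expect_identical(estimate_half_life(t, exp(1e-4 * t)), Inf)
  # 1% multiplicative noise: median over 20 chase cells within 5% of truth
  ch <- generate_chase(1.7, n_cells = 20, noise_sd = 0.01, seed = 9)
  est <- vapply(split(ch, ch$cell_id), function(d) {
    estimate_half_life(d$time_min, d$value)
  }, numeric(1))
  expect_lt(abs(median(est) - 1.7) / 1.7, 0.05)
})

test_that("peak detection reports local maxima above the height guard", {
  t <- seq(0, 100, by = 1)
  v <- sin(t / 5)
  pk <- detect_peaks(t, v, min_height = 0.5)
  expect_equal(nrow(pk), 3)
  expect_true(all(pk$height > 0.99))
  expect_equal(nrow(detect_peaks(t, v, min_height = 2)), 0)
})
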