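test_that("the SSR objective has the expected algebraic structure", {
  # evaluated at the generating parameters the SSR is numerically zero
  s0 <- hif_ssr(med, median_trace)
  expect_lt(s0, 1e-8 * sum(median_trace$value^2))
  # shifting n points by a constant c adds n * c^2
  shifted <- median_trace
  idx <- c(3, 50, 120)
  shifted$value[idx] <- shifted$value[idx] + 10
  expect_equal(hif_ssr(med, shifted) - s0, length(idx) * 100,
               tolerance = 1e-6)
  # a wrong parameter set scores strictly worse
  expect_gt(hif_ssr(hif_params(S = 2 * med$S), median_trace), s0 + 1)
  # deterministic
  expect_identical(hif_ssr(med, median_trace), hif_ssr(med, median_trace))
})

test_that("the error envelope applies the strict 1% rule", {
  d <- c(100, 150, 200, 150, 100)
  r <- classify_fit(d, d)
  expect_identical(r$class, "good")
  expect_identical(r$fraction_outside, 0)
  # range 100 -> envelope half-width 35; offset 36 puts every point outside
  r36 <- classify_fit(d + 36, d)
  expect_identical(r36$class, "bad")
  expect_identical(r36$fraction_outside, 1)
  # 200-point boundary fixture: 2 outside (1.0%) is good, 3 (1.5%) is bad
  data200 <- rep(c(0, 100), 100)
  m2 <- data200; m2[c(7, 151)] <- m2[c(7, 151)] + 36
  m3 <- data200; m3[c(7, 99, 151)] <- m3[c(7, 99, 151)] + 36
  expect_identical(classify_fit(m2, data200)$class, "good")
  expect_identical(classify_fit(m3, data200)$class, "bad")
  # scale invariance: multiplying model and data by c > 0 keeps the class
  expect_identical(classify_fit(0.01 * m3, 0.01 * data200)$class, "bad")
  expect_identical(classify_fit(250 * m2, 250 * data200)$class, "good")
  # zero-width envelope of a constant trace: only an exact match is good
  expect_identical(classify_fit(rep(5, 10), rep(5, 10))$class, "good")
  expect_identical(classify_fit(rep(5 + 1e-9, 10), rep(5, 10))$class, "bad")
})

test_that("free fit recovers the generating parameters from noiseless data", {
  fit <- hif_fit(median_trace, mode = "free", restarts = 0)
  expect_true(fit$converged)
  expect_identical(fit$envelope$class, "good")
  expect_true(all(abs(coef(fit) - med_true) / med_true < 0.02))
  # fit methods are coherent
  expect_equal(fitted(fit) + residuals(fit), median_trace$value)
  expect_equal(predict(fit), fitted(fit))
  expect_lt(sqrt(mean(residuals(fit)^2)), 1e-4 * max(median_trace$value))
})

test_that("constrained fitting honours the k, d box and never beats the free fit", {
  # constraint inactive when the truth is the median: same recovery
  fitc <- hif_fit(median_trace, mode = "constrained", median_params = med,
                  restarts = 0)
  expect_true(all(abs(coef(fitc) - med_true) / med_true < 0.02))
  # trace generated with k well outside the box: fitted k must stay inside
  p_out <- hif_params(k = med$k * 1.9)
  tr_out <- hif_simulate(p_out, protocol_deoxygenation(),
                         times = seq(0, 1260, 5))
  trace_out <- data.frame(time = tr_out$time, value = tr_out$x)
  fit_out <- hif_fit(trace_out, mode = "constrained", median_params = med,
                     restarts = 0)
  expect_lte(coef(fit_out)[["k"]], med$k * 1.5 + 1e-12)
  expect_gte(coef(fit_out)[["k"]], med$k * 0.5 - 1e-12)
  # the constrained optimum cannot undercut the free optimum
  fit_free <- hif_fit(trace_out, mode = "free", restarts = 0)
  expect_gte(fit_out$ssr, fit_free$ssr - 1e-6)
})

test_that("free fit stays within 15% of truth under 5% measurement noise", {
  set.seed(11)
  rng <- diff(range(median_trace$value))
  noisy <- data.frame(time = median_trace$time,
                      value = median_trace$value +
                        rnorm(nrow(median_trace), 0, 0.05 * rng))
  fit <- hif_fit(noisy, mode = "free", restarts = 1, seed = 2)
  expect_true(all(abs(coef(fit) - med_true) / med_true < 0.15))
  expect_identical(fit$envelope$class, "good")
})

test_that("re-oxygenation fits start from the hypoxic equilibrium", {
  prot <- protocol_reoxygenation()
  tr <- hif_simulate(med, prot, times = seq(0, 720, 5))
  # by construction the first sample sits at the hypoxic equilibrium
  expect_equal(tr$x[1], unname(hif_equilibrium(med, 0.14)["x"]),
               tolerance = 1e-6)
  fit <- hif_fit(data.frame(time = tr$time, value = tr$x), protocol = prot,
                 mode = "constrained", median_params = med, restarts = 0)
  expect_identical(fit$envelope$class, "good")
  expect_true(all(abs(coef(fit) - med_true) / med_true < 0.5))
})

test_that("fit input contracts are enforced", {
  expect_error(hif_fit(median_trace[1:10, ]), "20 samples")
  late <- median_trace[median_trace$time >= 100, ]
  expect_error(hif_fit(late), "span")
  expect_error(hif_fit(data.frame(time = 1:30, bad = 1:30)), "value")
})

test_that("population fitting builds the median cell and flags degenerates", {
  # three identical noiseless cells: medians equal the per-cell optimum
  tr3 <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(cell_id = paste0("c", i), time_min = median_trace$time,
               value = median_trace$value)
  }))
  pop <- hif_fit_population(tr3, restarts = 0)
  expect_true(all(abs(coef(pop) - coef(pop$free_fits[[1]])) /
                    coef(pop$free_fits[[1]]) < 1e-6))
  expect_true(all(pop$summary$envelope == "good"))
  # a constant trace is excluded from the free-fit stage
  trc <- rbind(tr3, data.frame(cell_id = "flat", time_min = median_trace$time,
                               value = rep(500, nrow(median_trace))))
  popc <- hif_fit_population(trc, restarts = 0)
  expect_false("flat" %in% names(popc$free_fits))
  expect_identical(unname(popc$classes["flat"]), "non_responder")
  expect_true(all(abs(coef(popc) - coef(pop)) < 1e-9))
  # all-degenerate cohorts abort with a diagnostic
  flat3 <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(cell_id = paste0("f", i), time_min = median_trace$time,
               value = rep(100 + i, nrow(median_trace)))
  }))
  expect_error(hif_fit_population(flat3), "bell-shaped")
  expect_error(hif_fit_population(tr3[tr3$cell_id %in% c("c1", "c2"), ]),
               "at least 3")
})
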