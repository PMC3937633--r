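#' Specification of a synthetic single-cell cohort
#'
#' Describes the statistical structure of a generated cohort of single-cell
#' fluorescence traces: the oxygen protocol, the sampling interval (5 min as
#' in the confocal experiments), cell-to-cell parameter heterogeneity
#' (lognormal, placed mainly on `S` and `gamma`, which absorb transfection
#' and laser-intensity variability; `k` and `d` deviations are capped at
#' `kd_cap` = 50\% of the median, mirroring the fitting constraint),
#' response-onset delays (uniform, emulating division-synchronized onsets),
#' additive Gaussian measurement noise scaled to each cell's dynamic range,
#' and the mix of responder / non-responder / multiple-peak cells.
#'
#' @param n_cells Number of cells.
#' @param protocol `"deoxygenation"` (1 h normoxia + 20 h hypoxia),
#'   `"reoxygenation"` (6 h hypoxia then 6 h normoxia) or an
#'   [oxygen_protocol()] object.
#' @param sampling_min Sampling interval, min.
#' @param heterogeneity Named vector of lognormal sdlog values for `S`,
#'   `gamma`, `k`, `d`.
#' @param kd_cap Cap on the fractional deviation of `k` and `d` from the
#'   median (draws are clamped to `median * (1 +/- kd_cap)`).
#' @param noise_sd Additive Gaussian noise sd as a fraction of each cell's
#'   noiseless dynamic range.
#' @param delay_range Range (min) of the per-cell uniform response-onset
#'   delay applied to the switch time.
#' @param class_mix Named fractions (`responder`, `non_responder`,
#'   `multiple`) summing to 1.
#' @param seed Integer seed; a fixed seed makes the cohort reproducible.
#' @return An object of class `"cohort_spec"`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_cells = 30,
                        protocol = "deoxygenation",
                        sampling_min = 5,
                        heterogeneity = c(S = 0.3, gamma = 0.3,
                                          k = 0.15, d = 0.15),
                        kd_cap = 0.5,
                        noise_sd = 0.05,
                        delay_range = c(0, 300),
                        class_mix = c(responder = 0.70,
                                      non_responder = 0.15,
                                      multiple = 0.15),
                        seed = 1L) {
  stopifnot(n_cells >= 1L, sampling_min > 0,
            all(c("S", "gamma", "k", "d") %in% names(heterogeneity)),
            all(heterogeneity >= 0), kd_cap > 0, kd_cap < 1,
            noise_sd >= 0, length(delay_range) == 2L,
            delay_range[1L] >= 0, delay_range[2L] >= delay_range[1L],
            all(c("responder", "non_responder", "multiple") %in%
                  names(class_mix)),
            all(class_mix >= 0))
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (is.character(protocol))
    protocol <- switch(match.arg(protocol,
                                 c("deoxygenation", "reoxygenation")),
                       deoxygenation = protocol_deoxygenation(),
                       reoxygenation = protocol_reoxygenation())
  stopifnot(inherits(protocol, "oxygen_protocol"))
  structure(list(n_cells = as.integer(n_cells), protocol = protocol,
                 sampling_min = sampling_min,
                 heterogeneity = heterogeneity, kd_cap = kd_cap,
                 noise_sd = noise_sd, delay_range = delay_range,
                 class_mix = class_mix, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d cells, %g-min sampling, seed %d\n",
              x$n_cells, x$sampling_min, x$seed))
  cat(sprintf("  class mix: %s\n",
              paste(names(x$class_mix), x$class_mix, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  heterogeneity (sdlog): %s; k,d capped at +/-%g%%\n",
              paste(names(x$heterogeneity), x$heterogeneity, sep = "=",
                    collapse = ", "), 100 * x$kd_cap))
  cat(sprintf("  noise %g of range; onset delay U[%g, %g] min\n",
              x$noise_sd, x$delay_range[1L], x$delay_range[2L]))
  invisible(x)
}

## draw one cell's parameters (seeded by caller)
.draw_params <- function(median, het, kd_cap) {
  draw <- function(m, sdlog) m * stats::rlnorm(1, 0, sdlog)
  S <- draw(median$S, het[["S"]])
  gamma <- draw(median$gamma, het[["gamma"]])
  clamp <- function(v, m) min(max(v, m * (1 - kd_cap)), m * (1 + kd_cap))
  k <- clamp(draw(median$k, het[["k"]]), median$k)
  d <- clamp(draw(median$d, het[["d"]]), median$d)
  hif_params(S = S, gamma = gamma, k = k, d = d)
}

#' Generate a synthetic single-cell cohort
#'
#' Draws per-cell parameters around the median cell, simulates each cell's
#' trajectory under the spec's oxygen protocol via the two-component model,
#' applies a per-cell response-onset delay (the switch is shifted later for
#' that cell), adds Gaussian measurement noise proportional to the cell's
#' dynamic range, and returns the traces together with a ground-truth
#' sidecar. Non-responders are cells whose reporter does not react: their
#' trajectory stays at the normoxic equilibrium (flat apart from noise).
#' Multiple-peak cells receive a temporary mid-hypoxia boost of `S` (a
#' generator device producing a second pulse, not a biological claim).
#'
#' @param spec A [cohort_spec()].
#' @param median Median-cell parameters ([hif_params()]).
#' @return An object of class `"hif_cohort"`: list with `traces` (long data
#'   frame `cell_id`, `time_min`, `value`), `truth` (per-cell true
#'   parameters, class and delay) and `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_cells = 3, seed = 7))
#' head(coh$traces)
#' @export
generate_cohort <- function(spec = cohort_spec(), median = hif_params()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(median, "hif_params"))
  prot <- spec$protocol
  times <- seq(prot$start[1L], prot$t_end, by = spec$sampling_min)
  classes <- c("responder", "non_responder", "multiple")
  .with_seed(spec$seed, {
    cls <- sample(classes, spec$n_cells, replace = TRUE,
                  prob = spec$class_mix[classes])
    out <- vector("list", spec$n_cells)
    truth <- vector("list", spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      p <- .draw_params(median, spec$heterogeneity, spec$kd_cap)
      delay <- stats::runif(1, spec$delay_range[1L], spec$delay_range[2L])
      x <- .simulate_cell(p, prot, times, cls[i], delay)
      rng <- max(x) - min(x)
      noise_scale <- spec$noise_sd * (if (rng > 0) rng else max(x))
      v <- x + stats::rnorm(length(x), 0, noise_scale)
      out[[i]] <- data.frame(cell_id = sprintf("cell_%03d", i),
                             time_min = times, value = v)
      truth[[i]] <- data.frame(cell_id = sprintf("cell_%03d", i),
                               class = cls[i], delay_min = delay,
                               S = p$S, gamma = p$gamma, k = p$k, d = p$d,
                               noise_sd_au = noise_scale)
    }
    structure(list(traces = do.call(rbind, out),
                   truth = do.call(rbind, truth),
                   spec = spec),
              class = "hif_cohort")
  })
}

## noiseless trajectory of one cell given its class and onset delay
.simulate_cell <- function(p, prot, times, class, delay) {
  if (class == "non_responder") {
    # reporter does not respond to the switch: stays at the initial
    # equilibrium of the first segment's oxygen state
    eq <- if (prot$state[1L] == "hypoxia")
      hif_equilibrium(p, prot$hypoxic_ratio) else hif_equilibrium(p, 1)
    return(rep(unname(eq["x"]), length(times)))
  }
  sw <- switch_times(prot)
  prot_i <- if (length(sw) && delay > 0) {
    oxygen_protocol(c(prot$start[1L], sw + delay), prot$state,
                    t_end = prot$t_end + delay,
                    hypoxic_ratio = prot$hypoxic_ratio)
  } else prot
  if (class == "multiple" && prot$state[1L] == "normoxia") {
    # temporary synthesis boost mid-hypoxia -> second pulse
    t_sw <- if (length(sw)) sw[1L] + delay else 0
    boost_on <- t_sw + 0.45 * (prot_i$t_end - t_sw)
    boost_off <- boost_on + 150
    x <- .simulate_boosted(p, prot_i, times, boost_on, boost_off,
                           s_factor = 2)
  } else {
    x <- hif_simulate(p, prot_i,
                      times = pmin(times, prot_i$t_end))$x
  }
  x
}

## piecewise simulation with S temporarily multiplied in [on, off]
.simulate_boosted <- function(p, prot, times, on, off, s_factor) {
  grid <- sort(unique(c(times, on, off)))
  hm <- protocol_multiplier(prot, grid)
  init <- if (prot$state[1L] == "hypoxia")
    hif_equilibrium(p, prot$hypoxic_ratio) else hif_equilibrium(p, 1)
  bounds <- sort(unique(c(prot$start, on, off, prot$t_end, max(times))))
  bounds <- bounds[bounds >= min(grid)]
  state <- as.numeric(init)
  xs <- NULL; ts <- NULL
  for (j in seq_len(length(bounds) - 1L)) {
    a <- bounds[j]; b <- bounds[j + 1L]
    seg_t <- sort(unique(c(a, grid[grid >= a & grid <= b], b)))
    pseg <- unclass(p)
    pseg$S <- p$S * (if (a >= on && b <= off) s_factor else 1)
    pseg$heff <- p$h * protocol_multiplier(prot, (a + b) / 2)
    sol <- deSolve::lsoda(state, seg_t, .rhs2, pseg,
                          rtol = 1e-6, atol = 1e-9)
    ts <- c(ts, sol[, 1L]); xs <- c(xs, sol[, 2L])
    state <- sol[nrow(sol), -1L]
  }
  xs[match(pmin(times, max(ts)), ts)]
}

#' Generate cycloheximide-chase decay traces
#'
#' Emulates a chase experiment: protein synthesis is blocked and the tagged
#' protein's fluorescence decays exponentially from a unit initial level at
#' rate `ln(2) / half_life`. Noise, when present, is multiplicative
#' lognormal (fluorescence stays positive).
#'
#' @param half_life_h True half-life, hours.
#' @param n_cells Number of decay traces.
#' @param noise_sd sdlog of the multiplicative lognormal noise (0 =
#'   noiseless).
#' @param seed Optional integer seed.
#' @param duration_h Chase duration, hours.
#' @param sampling_min Sampling interval, min.
#' @return Long data frame (`cell_id`, `time_min`, `value`).
#' @examples
#' ch <- generate_chase(1.7)
#' estimate_half_life(ch$time_min, ch$value)  # 1.7
#' @export
generate_chase <- function(half_life_h, n_cells = 1, noise_sd = 0,
                           seed = NULL, duration_h = 24, sampling_min = 5) {
  stopifnot(half_life_h > 0, n_cells >= 1, noise_sd >= 0, duration_h > 0)
  times <- seq(0, duration_h * 60, by = sampling_min)
  rate <- log(2) / (half_life_h * 60)
  .with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_cells), function(i) {
      v <- exp(-rate * times)
      if (noise_sd > 0) v <- v * stats::rlnorm(length(v), 0, noise_sd)
      data.frame(cell_id = sprintf("chase_%03d", i),
                 time_min = times, value = v)
    }))
  })
}
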