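#' p53-Mdm2 negative-feedback model parameters
#'
#' A compact fast-binding p53-Mdm2 oscillator: p53 is produced at a constant
#' rate, degraded slowly when free and rapidly when bound in a p53-Mdm2
#' complex; p53 activates Mdm2 transcription (cooperativity 2); Mdm2 mRNA is
#' translated into Mdm2 protein; mRNA and protein turn over linearly. The
#' complex is assumed at fast binding equilibrium with dissociation constant
#' `K`, so with total p53 `P` and total Mdm2 `M` the complex is the quadratic
#' quasi-steady-state root
#' \deqn{C = \frac{(P+M+K) - \sqrt{(P+M+K)^2 - 4PM}}{2}.}
#' The states are total p53, Mdm2 mRNA and total Mdm2:
#' \deqn{dP/dt = \sigma - \alpha(P-C) - \delta C,}
#' \deqn{dm/dt = k_t (P-C)^2 - \beta m, \quad dM/dt = k_{tl} m - g M.}
#' The single coupling hook is \eqn{\delta}, the degradation rate of
#' Mdm2-complexed p53: hypoxia inhibits it (HIF binds Mdm2), which is what
#' the HIF-dependent rate \eqn{\delta(x) = A e^{-Bx}} of
#' [calibrate_delta()] feeds.
#'
#' Default constants are this package's own (the published constants of the
#' model family are not reproduced here); they are synthetic values fixed so
#' that the system has the three regimes the coupling exploits: a stable low
#' attractor at the normoxic `delta_norm`, a limit cycle at the hypoxic
#' `delta_hyp` (period about 3 h) and a stable high state as `delta` tends
#' to 0. All rates are per minute; concentrations in arbitrary units (AU).
#'
#' @param sigma p53 synthesis rate, AU min^-1.
#' @param alpha Basal degradation rate of free p53, min^-1.
#' @param K p53-Mdm2 dissociation constant, AU.
#' @param kt Mdm2 transcription rate constant, AU^-1 min^-1.
#' @param beta Mdm2 mRNA degradation rate, min^-1.
#' @param ktl Mdm2 translation rate, min^-1.
#' @param g Mdm2 protein degradation rate, min^-1.
#' @param delta_norm Degradation rate of complexed p53 at the normoxic HIF
#'   equilibrium, min^-1.
#' @param delta_hyp Same at the hypoxic HIF equilibrium, min^-1
#'   (`delta_hyp <= delta_norm`).
#' @return An object of class `"p53_params"`.
#' @seealso [calibrate_delta()], [run_steady_hif()], [run_dynamic_hif()]
#' @export
p53_params <- function(sigma = 35 / 60, alpha = 0.5 / 60, K = 0.2,
                       kt = 0.13 / 60, beta = 0.55 / 60, ktl = 1.5 / 60,
                       g = 1.7 / 60,
                       delta_norm = 100 / 60, delta_hyp = 10 / 60) {
  vals <- c(sigma = sigma, alpha = alpha, K = K, kt = kt, beta = beta,
            ktl = ktl, g = g, delta_norm = delta_norm,
            delta_hyp = delta_hyp)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all p53 model parameters must be finite and > 0")
  if (delta_hyp > delta_norm) stop("'delta_hyp' must not exceed 'delta_norm'")
  structure(as.list(vals), class = "p53_params")
}

#' @export
print.p53_params <- function(x, ...) {
  cat("p53-Mdm2 feedback model parameters (per-minute rates)\n")
  v <- unlist(unclass(x))
  print(signif(v, 4))
  invisible(x)
}

## quadratic quasi-steady-state complex, numerically stable form
.p53_complex <- function(P, M, K) {
  b <- P + M + K
  2 * P * M / (b + sqrt(pmax(b^2 - 4 * P * M, 0)))
}

.p53_rhs <- function(t, st, p) {
  P <- st[[1L]]; m <- st[[2L]]; M <- st[[3L]]
  C <- .p53_complex(P, M, p$K)
  pf <- P - C
  list(c(p$sigma - p$alpha * pf - p$delta_fun(t) * C,
         p$kt * pf^2 - p$beta * m,
         p$ktl * m - p$g * M))
}

#' Calibrate the HIF-dependent p53 degradation rate
#'
#' The degradation rate of Mdm2-complexed p53 is modelled as an explicit
#' function of HIF, \eqn{\delta(x) = A e^{-Bx}}, with the constants chosen
#' so that it matches the host p53 model's switched rates at the HIF
#' equilibrium levels: \eqn{\delta(x^*_{norm}) = \delta_{norm}} and
#' \eqn{\delta(x^*_{hyp}) = \delta_{hyp}}. In closed form
#' \deqn{B = \ln(\delta_{norm}/\delta_{hyp}) / (x^*_{hyp} - x^*_{norm}),
#'       \quad A = \delta_{norm} e^{B x^*_{norm}}.}
#' Because \eqn{\delta} is monotone decreasing in `x`, transient HIF
#' overshoot above the hypoxic equilibrium drives \eqn{\delta} below
#' `delta_hyp`, the mechanism behind the elevated transitory p53 levels
#' under dynamic HIF input.
#'
#' @param x_norm_eq,x_hyp_eq Normoxic and hypoxic HIF equilibria, AU
#'   (`x_hyp_eq > x_norm_eq >= 0`).
#' @param delta_norm,delta_hyp Target degradation rates at those equilibria
#'   (`delta_norm >= delta_hyp > 0`).
#' @return An object of class `"p53_coupling"`: list with `A`, `B` and a
#'   function `delta(x)`.
#' @examples
#' cal <- calibrate_delta(96.95, 325.59, 100 / 60, 10 / 60)
#' cal$delta(96.95) * 60  # 100
#' @export
calibrate_delta <- function(x_norm_eq, x_hyp_eq, delta_norm, delta_hyp) {
  stopifnot(is.numeric(x_norm_eq), is.numeric(x_hyp_eq),
            x_norm_eq >= 0, delta_hyp > 0, delta_norm >= delta_hyp)
  if (x_hyp_eq <= x_norm_eq) {
    if (delta_norm == delta_hyp && x_hyp_eq == x_norm_eq) {
      # degenerate but feasible: constant delta
      B <- 0
    } else {
      stop("infeasible calibration: need x_hyp_eq > x_norm_eq ",
           "(or equal deltas)")
    }
  } else {
    B <- log(delta_norm / delta_hyp) / (x_hyp_eq - x_norm_eq)
  }
  A <- delta_norm * exp(B * x_norm_eq)
  structure(list(A = A, B = B,
                 x_norm_eq = x_norm_eq, x_hyp_eq = x_hyp_eq,
                 delta_norm = delta_norm, delta_hyp = delta_hyp,
                 delta = function(x) A * exp(-B * x)),
            class = "p53_coupling")
}

#' @export
print.p53_coupling <- function(x, ...) {
  cat("HIF-dependent p53 degradation rate delta(x) = A exp(-B x)\n")
  cat(sprintf("  A = %.6g /min, B = %.6g /AU\n", x$A, x$B))
  cat(sprintf("  delta(%g AU) = %.4g /min (normoxic), delta(%g AU) = %.4g /min (hypoxic)\n",
              x$x_norm_eq, x$delta(x$x_norm_eq),
              x$x_hyp_eq, x$delta(x$x_hyp_eq)))
  invisible(x)
}

#' Attractor of the p53 model at a fixed degradation rate
#'
#' Integrates the model for a long horizon at constant `delta` and returns
#' the final state (the stable fixed point when one exists; for oscillatory
#' `delta` values the returned state is a point on the limit cycle).
#'
#' @param params [p53_params()].
#' @param delta Constant degradation rate of complexed p53, min^-1.
#' @param horizon_min Integration horizon.
#' @return Named state vector `P` (total p53), `m` (Mdm2 mRNA), `M` (total
#'   Mdm2).
#' @export
p53_attractor <- function(params, delta, horizon_min = 60 * 2000) {
  stopifnot(inherits(params, "p53_params"), delta > 0)
  p <- unclass(params)
  p$delta_fun <- function(t) delta
  out <- deSolve::lsoda(c(P = params$sigma / params$alpha / 100,
                          m = 0.01, M = 0.01),
                        seq(0, horizon_min, length.out = 201L), .p53_rhs, p,
                        rtol = 1e-9, atol = 1e-11)
  st <- out[nrow(out), -1L]
  names(st) <- c("P", "m", "M")
  st
}

## shared driver: integrate the p53 model under a delta(t) time course
.p53_run <- function(params, delta_fun, times, init) {
  p <- unclass(params)
  p$delta_fun <- delta_fun
  sol <- deSolve::lsoda(init, times, .p53_rhs, p, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0) stop("p53 solver failed")
  sol
}

#' p53 dynamics under steady HIF dependence
#'
#' The hypoxic switch is represented as an instantaneous jump of HIF from
#' its low normoxic equilibrium to its high hypoxic equilibrium at `t = 0`
#' (steady HIF dependence): the p53 model, started on its normoxic
#' attractor, sees the degradation rate step from `delta(x_norm)` to
#' `delta(x_hyp)`. The p53 level then shows one transitory peak followed by
#' sustained regular oscillations.
#'
#' @param params [p53_params()].
#' @param hif Parameters of the HIF model supplying the equilibria
#'   ([hif_params()] or calibrated [hif_params4()]); hypoxic equilibria use
#'   the model's hypoxic ratio(s).
#' @param t_end End of the simulation, min.
#' @param dt Output step, min.
#' @param switch `"hypoxia"` for the normoxia-to-hypoxia step at `t = 0`,
#'   `"none"` for a constant normoxic control, `"reverse"` for the
#'   hypoxia-to-normoxia step (started on the hypoxic state).
#' @return A `"p53_trajectory"`: data frame `time`, `x` (HIF input), `delta`
#'   (min^-1), `p53`, `mdm2`, `mdm2_mrna`, with the calibration and
#'   parameters as attributes.
#' @examples
#' \donttest{
#' tr <- run_steady_hif(t_end = 60 * 24)
#' oscillation_summary(tr)$n_transitory
#' }
#' @export
run_steady_hif <- function(params = p53_params(), hif = hif_params(),
                           t_end = 60 * 72, dt = 2,
                           switch = c("hypoxia", "none", "reverse")) {
  switch <- match.arg(switch)
  stopifnot(inherits(params, "p53_params"))
  eqs <- .hif_equilibria(hif)
  cal <- calibrate_delta(eqs["norm"], eqs["hyp"],
                         params$delta_norm, params$delta_hyp)
  times <- seq(0, t_end, by = dt)
  xfun <- switch(switch,
                 hypoxia = function(t) ifelse(t < 0, eqs["norm"], eqs["hyp"]),
                 none = function(t) rep(eqs["norm"], length(t)),
                 reverse = function(t) ifelse(t < 0, eqs["hyp"], eqs["norm"]))
  init <- p53_attractor(params, if (switch == "reverse")
    params$delta_hyp else params$delta_norm)
  sol <- .p53_run(params, function(t) cal$delta(xfun(t)), times, init)
  .p53_traj(sol, xfun(times), cal, params)
}

#' p53 dynamics under dynamic HIF dependence
#'
#' The hypoxic switch drives the full transient HIF response of the
#' four-component HIF-PHD model (wild type or PHD2-knockout), which is
#' coupled one-way into the p53 model: the HIF course `x(t)` is solved
#' first on a dense grid, interpolated, and fed through
#' \eqn{\delta(x) = A e^{-Bx}} evaluated continuously along the solution.
#' No feedback from p53 to HIF exists, so the HIF trajectory is identical
#' with or without the p53 layer.
#'
#' @param params [p53_params()].
#' @param hif Calibrated [hif_params4()] wild-type parameter set.
#' @param scenario `"WT"` or `"shPHD2"` (PHD2 removed in silico).
#' @param protocol De-oxygenation [oxygen_protocol()] for the HIF layer; it
#'   is extended at its final hypoxic level if shorter than `t_end`.
#' @param t_end,dt Simulation horizon and output step, min.
#' @return A `"p53_trajectory"` (see [run_steady_hif()]).
#' @examples
#' \donttest{
#' wt <- calibrate_basal_synthesis(hif_params4())
#' tr <- run_dynamic_hif(hif = wt, t_end = 60 * 24)
#' }
#' @export
run_dynamic_hif <- function(params = p53_params(),
                            hif = calibrate_basal_synthesis(hif_params4()),
                            scenario = c("WT", "shPHD2"),
                            protocol = NULL,
                            t_end = 60 * 72, dt = 2) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "p53_params"), inherits(hif, "hif_params4"))
  if (is.null(protocol))
    protocol <- oxygen_protocol(c(-60, 0), c("normoxia", "hypoxia"),
                                t_end = t_end)
  if (protocol$t_end < t_end)
    protocol <- oxygen_protocol(protocol$start, protocol$state, t_end,
                                hypoxic_ratio = protocol$hypoxic_ratio)
  # calibration always uses the wild-type equilibria: the coupling is a
  # property of the cell line's normal operating points
  eqs <- .hif_equilibria(hif)
  cal <- calibrate_delta(eqs["norm"], eqs["hyp"],
                         params$delta_norm, params$delta_hyp)
  ko <- knockout_simulation(hif,
                            knockout = if (scenario == "shPHD2") "PHD2"
                            else "none",
                            protocol = protocol, dt = min(dt, 2))
  traj <- ko$trajectory
  xfun <- stats::approxfun(traj$time, traj$x, rule = 2)
  times <- seq(max(0, protocol$start[1L]), t_end, by = dt)
  init <- p53_attractor(params, cal$delta(xfun(times[1L])))
  sol <- .p53_run(params, function(t) cal$delta(xfun(t)), times, init)
  .p53_traj(sol, xfun(times), cal, params, scenario = scenario,
            hif_trajectory = traj)
}

.hif_equilibria <- function(hif) {
  if (inherits(hif, "hif_params")) {
    c(norm = unname(hif_equilibrium(hif, 1)["x"]),
      hyp = unname(hif_equilibrium(hif, 0.14)["x"]))
  } else if (inherits(hif, "hif_params4")) {
    c(norm = unname(hif_equilibrium(hif, 1)["x"]),
      hyp = unname(.equilibrium4_mult(hif, hif$oxygen_ratio)["x"]))
  } else stop("'hif' must be an hif_params or hif_params4 object")
}

.p53_traj <- function(sol, x, cal, params, scenario = NULL,
                      hif_trajectory = NULL) {
  df <- data.frame(time = sol[, 1L], x = as.numeric(x),
                   delta = cal$delta(as.numeric(x)),
                   p53 = sol[, 2L], mdm2_mrna = sol[, 3L],
                   mdm2 = sol[, 4L])
  structure(df, coupling = cal, params = params, scenario = scenario,
            hif_trajectory = hif_trajectory,
            class = c("p53_trajectory", "data.frame"))
}

#' @export
print.p53_trajectory <- function(x, ...) {
  cat(sprintf("p53-Mdm2 trajectory under %s HIF input: %d points over %.1f h\n",
              if (is.null(attr(x, "scenario"))) "steady"
              else paste("dynamic", attr(x, "scenario")),
              nrow(x), x$time[nrow(x)] / 60))
  cat(sprintf("  p53 range %.3g-%.3g AU\n", min(x$p53), max(x$p53)))
  invisible(x)
}

#' @export
plot.p53_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time / 60, x$x, type = "l", col = "darkgreen",
                 xlab = "time (h)", ylab = "HIF (AU)", ...)
  graphics::plot(x$time / 60, x$p53, type = "l", col = "purple",
                 xlab = "time (h)", ylab = "p53 (AU)", ...)
  invisible(x)
}

#' Peak structure of a p53 time course
#'
#' Summarizes the oscillatory structure of a p53 trajectory with the same
#' peak machinery used for HIF traces ([detect_peaks()]). Peaks are local
#' maxima higher than `min_height_factor` times the normoxic attractor p53
#' level. The established oscillation train is characterized by the median
#' height of the later half of the peaks; peaks exceeding
#' `transitory_ratio` times that train height are the transitory phase, and
#' the oscillation onset is the first peak after the last transitory peak.
#'
#' @param trajectory A `"p53_trajectory"`, or a data frame with `time` and
#'   `p53` columns.
#' @param baseline Normoxic attractor p53 level; computed from the
#'   trajectory's parameters when `NULL`.
#' @param min_height_factor Peak height guard, in units of `baseline`.
#' @param transitory_ratio Height ratio above the train median that marks a
#'   peak as transitory.
#' @return List with `peaks` (data frame `time`, `height`), `n_peaks`,
#'   `n_transitory`, `onset_time` (min; `NA` when no regular train exists),
#'   `period` (median inter-peak interval of the train, min), `ipi_cv`
#'   (coefficient of variation of the train's inter-peak intervals; small
#'   values mean regular spacing) and `oscillating` (at least 3 train peaks
#'   with `ipi_cv < 0.2`).
#' @export
oscillation_summary <- function(trajectory, baseline = NULL,
                                min_height_factor = 2,
                                transitory_ratio = 1.25) {
  df <- as.data.frame(trajectory)
  stopifnot(all(c("time", "p53") %in% names(df)))
  if (is.null(baseline)) {
    params <- attr(trajectory, "params")
    baseline <- if (!is.null(params))
      unname(p53_attractor(params, params$delta_norm)["P"])
    else stop("supply 'baseline' for plain data frames")
  }
  pk <- detect_peaks(df$time, df$p53,
                     min_height = min_height_factor * baseline)
  out <- list(peaks = pk, n_peaks = nrow(pk), n_transitory = 0L,
              onset_time = NA_real_, period = NA_real_,
              ipi_cv = NA_real_, oscillating = FALSE)
  if (nrow(pk) == 0L) return(out)
  train_med <- stats::median(pk$height[ceiling(nrow(pk) / 2):nrow(pk)])
  transitory <- pk$height >= transitory_ratio * train_med
  out$n_transitory <- sum(transitory)
  train <- if (any(transitory)) {
    last_tr <- max(which(transitory))
    if (last_tr < nrow(pk)) pk[(last_tr + 1L):nrow(pk), ] else pk[0L, ]
  } else pk
  if (nrow(train) >= 1L) out$onset_time <- train$time[1L]
  if (nrow(train) >= 3L) {
    ipi <- diff(train$time)
    out$period <- stats::median(ipi)
    out$ipi_cv <- stats::sd(ipi) / mean(ipi)
    out$oscillating <- nrow(train) >= 3L && out$ipi_cv < 0.2
  }
  out
}
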