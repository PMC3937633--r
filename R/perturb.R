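#' One-at-a-time parameter sensitivity scan around the median cell
#'
#' Perturbs each parameter of the two-component model individually over a
#' multiplier grid (25\% steps up to +/-75\% by default, so 7 runs per
#' parameter including the baseline), simulates the de-oxygenation response
#' of every perturbed cell from its OWN normoxic equilibrium, and normalizes
#' each trajectory by its own pre-stimulation equilibrium so that every
#' normalized run starts at exactly 1. Per run the summary records the
#' normalized and absolute peak amplitude, time to peak after the switch and
#' the supra-half-maximum excursion duration of the normalized trajectory.
#'
#' @param params Median-cell parameters ([hif_params()]).
#' @param protocol De-oxygenation [oxygen_protocol()] (normoxic first
#'   segment).
#' @param parameters Which parameters to scan.
#' @param multipliers Multiplier grid (all > 0; 1 must be interpretable as
#'   the baseline).
#' @param dt Output resolution of the simulated trajectories, min.
#' @return An object of class `"hif_sensitivity"`: list with `summary` (data
#'   frame: `parameter`, `multiplier`, `peak_norm`, `peak_abs`,
#'   `time_to_peak`, `duration`, `equilibrium`) and `trajectories` (named
#'   list of data frames `time`, one normalized column per multiplier).
#' @examples
#' \donttest{
#' sens <- sensitivity_scan(parameters = "k", multipliers = c(0.5, 1, 1.5))
#' subset(sens$summary, parameter == "k")
#' }
#' @export
sensitivity_scan <- function(params = hif_params(),
                             protocol = protocol_deoxygenation(),
                             parameters = c("S", "gamma", "k", "d"),
                             multipliers = seq(0.25, 1.75, by = 0.25),
                             dt = 1) {
  stopifnot(inherits(params, "hif_params"),
            all(parameters %in% c("S", "gamma", "k", "d")),
            all(multipliers > 0))
  if (protocol$state[1L] != "normoxia")
    stop("sensitivity scan expects a de-oxygenation protocol")
  t_sw <- switch_times(protocol)[1L]
  times <- seq(protocol$start[1L], protocol$t_end, by = dt)
  rows <- list(); trajs <- list()
  for (par in parameters) {
    mat <- matrix(NA_real_, nrow = length(times),
                  ncol = length(multipliers))
    for (j in seq_along(multipliers)) {
      p <- params
      p[[par]] <- params[[par]] * multipliers[j]
      eq <- hif_equilibrium(p, 1)
      sim <- hif_simulate(p, protocol, times = times)
      xn <- sim$x / eq[["x"]]
      exc <- trace_excursions(times, xn, response_threshold(xn))
      dur <- if (nrow(exc)) exc$duration[1L] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, multiplier = multipliers[j],
        peak_norm = max(xn), peak_abs = max(sim$x),
        time_to_peak = times[which.max(xn)] - t_sw,
        duration = dur, equilibrium = eq[["x"]])
      mat[, j] <- xn
    }
    tr <- data.frame(time = times, mat)
    names(tr) <- c("time", paste0("m", multipliers))
    trajs[[par]] <- tr
  }
  structure(list(summary = do.call(rbind, rows), trajectories = trajs,
                 params = params, protocol = protocol),
            class = "hif_sensitivity")
}

#' @export
print.hif_sensitivity <- function(x, ...) {
  cat("One-at-a-time sensitivity scan (",
      nrow(x$summary), "runs )\n")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.hif_sensitivity <- function(x, parameter = NULL, ...) {
  par_names <- names(x$trajectories)
  if (is.null(parameter)) parameter <- par_names[1L]
  tr <- x$trajectories[[parameter]]
  graphics::matplot(tr$time, as.matrix(tr[, -1L]), type = "l", lty = 1,
                    xlab = "time (min)",
                    ylab = "HIF (normalized to equilibrium)",
                    main = paste("varying", parameter), ...)
  graphics::legend("topright", legend = names(tr)[-1L], lty = 1,
                   col = seq_len(ncol(tr) - 1L), bty = "n")
  invisible(x)
}

#' In silico PHD knockout on the four-component model
#'
#' Removes one PHD isoform entirely (basal synthesis, HIF induction and
#' initial protein all set to zero), re-equilibrates the remaining system in
#' the pre-switch oxygen state, simulates the protocol and classifies the
#' resulting HIF time course with the same response classifier used for
#' experimental traces.
#'
#' @param params Calibrated [hif_params4()] (wild type).
#' @param knockout `"none"` (wild type), `"PHD1"`, `"PHD2"` or `"PHD3"`.
#' @param protocol An [oxygen_protocol()].
#' @param dt Output resolution, min.
#' @return An object of class `"hif_knockout"`: list with `knockout`,
#'   `trajectory` (`"hif_trajectory"`), `response` (the [classify_response()]
#'   result for the simulated HIF course) and `params` (the knockout
#'   parameter set).
#' @examples
#' \donttest{
#' wt <- calibrate_basal_synthesis(hif_params4())
#' ko <- knockout_simulation(wt, "PHD2")
#' ko$response$class  # prolonged
#' }
#' @export
knockout_simulation <- function(params, knockout = c("none", "PHD1",
                                                     "PHD2", "PHD3"),
                                protocol = protocol_deoxygenation(),
                                dt = 1) {
  stopifnot(inherits(params, "hif_params4"))
  knockout <- match.arg(knockout)
  p <- params
  idx <- match(knockout, c("PHD1", "PHD2", "PHD3"))
  if (!is.na(idx)) {
    p$S_basal[idx] <- 0
    p$k[idx] <- 0
    if (sum(p$S_basal + p$k) == 0)
      stop("knockout removes all remaining PHD synthesis; infeasible")
  }
  times <- seq(protocol$start[1L], protocol$t_end, by = dt)
  # re-equilibrate in the first segment's oxygen state; the removed isoform
  # has no synthesis left, so its equilibrium level is automatically zero
  traj <- hif_simulate(p, protocol, times = times)
  resp <- classify_response(traj$time, traj$x)
  structure(list(knockout = knockout, trajectory = traj, response = resp,
                 params = p),
            class = "hif_knockout")
}

#' @export
print.hif_knockout <- function(x, ...) {
  cat(sprintf("In silico knockout: %s\n", x$knockout))
  print(x$trajectory)
  cat(sprintf("HIF response class: %s", x$response$class))
  if (length(x$response$durations))
    cat(sprintf(" (duration %s min)",
                paste(signif(x$response$durations, 4), collapse = ", ")))
  cat("\n")
  invisible(x)
}
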