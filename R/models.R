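#' Time derivatives of the HIF-PHD feedback models
#'
#' Evaluates the right-hand side of the two-component model (`state = c(x, y)`)
#' or the four-component model (`state = c(x, y1, y2, y3)`) at a given state
#' and hydroxylation multiplier. Mainly useful for equilibrium checks and
#' tests; [hif_simulate()] integrates the same functions.
#'
#' @param params An [hif_params()] or [hif_params4()] object.
#' @param state Non-negative numeric state vector (length 2 or 4).
#' @param h_mult Multiplier applied to the hydroxylation factor(s): 1 in
#'   normoxia, the hypoxic ratio in hypoxia.
#' @return Named numeric vector of time derivatives, AU min^-1.
#' @examples
#' hif_derivs(hif_params(), c(x = 100, y = 0))  # dx/dt equals S when y = 0
#' @export
hif_derivs <- function(params, state, h_mult = 1) {
  UseMethod("hif_derivs")
}

#' @export
hif_derivs.hif_params <- function(params, state, h_mult = 1) {
  if (length(state) != 2L) stop("two-component state must have length 2")
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and non-negative")
  x <- state[[1L]]; y <- state[[2L]]
  h <- params$h * h_mult
  c(x = params$S - h * y * x / (params$gamma + x),
    y = params$k * x - params$d * y)
}

#' @export
hif_derivs.hif_params4 <- function(params, state, h_mult = 1) {
  if (length(state) != 4L) stop("four-component state must have length 4")
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and non-negative")
  if (anyNA(params$S_basal))
    stop("basal synthesis rates are NA; run calibrate_basal_synthesis() first")
  x <- state[[1L]]; y <- state[2:4]
  h <- params$h * h_mult
  dx <- params$S - x / (params$gamma + x) * sum(h * y)
  dy <- params$S_basal + params$k * x - params$d * y
  c(x = dx, y1 = dy[[1L]], y2 = dy[[2L]], y3 = dy[[3L]])
}

#' Equilibrium state at a fixed hydroxylation multiplier
#'
#' For the two-component model the steady state solves
#' \eqn{y^* = k x^*/d} with \eqn{x^*} the positive root of the quadratic
#' \eqn{h (k/d) x^2 - S x - S\gamma = 0}, returned in closed form. For the
#' four-component model the steady state of each PHD isoform given `x` is
#' \eqn{y_i^* = (S_i + k_i x)/d_i} and \eqn{x^*} is found by root bracketing
#' of the scalar balance equation.
#'
#' @inheritParams hif_derivs
#' @param h_mult Hydroxylation multiplier (1 normoxia, hypoxic ratio hypoxia).
#' @return Named state vector with all time derivatives zero.
#' @examples
#' hif_equilibrium(hif_params(), 1)      # x* = y* ~ 96.95 AU
#' hif_equilibrium(hif_params(), 0.14)   # hypoxic x* ~ 325.6 AU
#' @export
hif_equilibrium <- function(params, h_mult = 1) {
  UseMethod("hif_equilibrium")
}

#' @export
hif_equilibrium.hif_params <- function(params, h_mult = 1) {
  stopifnot(is.numeric(h_mult), length(h_mult) == 1L, h_mult > 0, h_mult <= 1)
  if (params$S == 0) return(c(x = 0, y = 0))
  a <- params$h * h_mult * params$k / params$d
  disc <- params$S^2 + 4 * a * params$S * params$gamma
  stopifnot(disc > 0)  # guaranteed for positive parameters
  x <- (params$S + sqrt(disc)) / (2 * a)
  c(x = x, y = params$k * x / params$d)
}

#' @export
hif_equilibrium.hif_params4 <- function(params, h_mult = 1) {
  stopifnot(is.numeric(h_mult), length(h_mult) == 1L, h_mult > 0, h_mult <= 1)
  if (anyNA(params$S_basal))
    stop("basal synthesis rates are NA; run calibrate_basal_synthesis() first")
  h <- params$h * h_mult
  if (sum(h * (params$S_basal + params$k)) == 0)
    stop("no PHD synthesis remains; HIF has no finite equilibrium")
  ystar <- function(x) (params$S_basal + params$k * x) / params$d
  bal <- function(x) params$S - x / (params$gamma + x) * sum(h * ystar(x))
  if (params$S == 0) {
    x <- 0
  } else {
    hi <- 1
    while (bal(hi) > 0) hi <- hi * 10
    x <- stats::uniroot(bal, c(0, hi), tol = 1e-12)$root
  }
  y <- ystar(x)
  c(x = x, y1 = y[[1L]], y2 = y[[2L]], y3 = y[[3L]])
}

## deSolve-facing RHS wrappers (state already validated at entry points;
## solvers may transiently probe slightly negative values)
.rhs2 <- function(t, st, p) {
  x <- st[[1L]]; y <- st[[2L]]
  list(c(p$S - p$heff * y * x / (p$gamma + x),
         p$k * x - p$d * y))
}

.rhs4 <- function(t, st, p) {
  x <- st[[1L]]; y <- st[2:4]
  list(c(p$S - x / (p$gamma + x) * sum(p$heff * y),
         p$S_basal + p$k * x - p$d * y))
}

## effective hydroxylation factor(s) for a protocol state
.heff <- function(params, state, protocol) {
  mult <- if (identical(state, "hypoxia")) {
    if (inherits(params, "hif_params4")) params$oxygen_ratio
    else protocol$hypoxic_ratio
  } else 1
  params$h * mult
}

#' Simulate a HIF-PHD model under an oxygen protocol
#'
#' Integrates the two- or four-component model with `deSolve::lsoda`
#' (stiff-capable), restarting the solver at every protocol switch so the
#' discontinuous change in hydroxylation rate is never smoothed over.
#'
#' @param params An [hif_params()] or [hif_params4()] object.
#' @param protocol An [oxygen_protocol()]; defaults to the de-oxygenation
#'   protocol (1 h normoxia, 20 h hypoxia).
#' @param times Output time grid, min; defaults to 1-min resolution over the
#'   protocol. Must be increasing and lie within the protocol.
#' @param init Initial state vector, or `"equilibrium"` to start at the
#'   equilibrium of the first protocol segment.
#' @param rtol,atol Solver tolerances.
#' @return A `"hif_trajectory"`: a data frame with column `time` (min), `x`
#'   (HIF, AU) and the PHD column(s) (`y` or `y1`,`y2`,`y3`), carrying the
#'   parameters and protocol as attributes.
#' @examples
#' tr <- hif_simulate(hif_params(), protocol_deoxygenation())
#' max(tr$x)  # pulse amplitude
#' @export
hif_simulate <- function(params, protocol = protocol_deoxygenation(),
                         times = NULL, init = "equilibrium",
                         rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(params, c("hif_params", "hif_params4")),
            inherits(protocol, "oxygen_protocol"))
  two <- inherits(params, "hif_params")
  if (is.null(times))
    times <- seq(protocol$start[1L], protocol$t_end, by = 1)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (times[1L] < protocol$start[1L] || times[length(times)] > protocol$t_end)
    stop("'times' must lie within the protocol interval")
  rhs <- if (two) .rhs2 else .rhs4
  if (identical(init, "equilibrium")) {
    init <- if (protocol$state[1L] == "hypoxia") {
      if (two) hif_equilibrium(params, protocol$hypoxic_ratio)
      else .equilibrium4_mult(params, params$oxygen_ratio)
    } else {
      hif_equilibrium(params, 1)
    }
  }
  init <- as.numeric(init)
  if (length(init) != (if (two) 2L else 4L) || any(init < 0))
    stop("invalid initial state")
  nm <- if (two) c("x", "y") else c("x", "y1", "y2", "y3")
  names(init) <- nm

  bounds <- c(protocol$start, protocol$t_end)
  out_t <- numeric(0); out_s <- NULL
  state <- init
  for (i in seq_along(protocol$start)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    if (b <= times[1L] || a >= times[length(times)]) {
      seg_t <- c(a, b)
    } else {
      seg_t <- sort(unique(c(a, times[times >= a & times <= b], b)))
    }
    p <- unclass(params)
    p$heff <- .heff(params, protocol$state[i], protocol)
    sol <- try(deSolve::lsoda(state, seg_t, rhs, p,
                              rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(sol, "try-error") ||
        attr(sol, "istate")[1L] < 0 || nrow(sol) < length(seg_t))
      stop(sprintf("solver failed in protocol segment %d (%s, [%g, %g] min)",
                   i, protocol$state[i], a, b))
    out_t <- c(out_t, sol[, 1L])
    out_s <- rbind(out_s, sol[, -1L, drop = FALSE])
    state <- sol[nrow(sol), -1L]
  }
  keep <- match(times, out_t)
  stopifnot(!anyNA(keep))
  df <- data.frame(time = times, out_s[keep, , drop = FALSE])
  names(df) <- c("time", nm)
  rownames(df) <- NULL
  structure(df, params = params, protocol = protocol,
            class = c("hif_trajectory", "data.frame"))
}

## 4C equilibrium with per-isoform multiplier vector
.equilibrium4_mult <- function(params, mult) {
  h <- params$h * mult
  ystar <- function(x) (params$S_basal + params$k * x) / params$d
  bal <- function(x) params$S - x / (params$gamma + x) * sum(h * ystar(x))
  hi <- 1
  while (bal(hi) > 0) hi <- hi * 10
  x <- stats::uniroot(bal, c(0, hi), tol = 1e-12)$root
  y <- ystar(x)
  c(x = x, y1 = y[[1L]], y2 = y[[2L]], y3 = y[[3L]])
}

#' @export
print.hif_trajectory <- function(x, ...) {
  cat(sprintf("HIF-PHD trajectory: %d time points over [%g, %g] min, %s model\n",
              nrow(x), x$time[1L], x$time[nrow(x)],
              if (ncol(x) == 3L) "two-component" else "four-component"))
  cat(sprintf("  HIF range: %.4g - %.4g AU\n", min(x$x), max(x$x)))
  invisible(x)
}

#' @export
plot.hif_trajectory <- function(x, ...) {
  prot <- attr(x, "protocol")
  graphics::matplot(x$time, as.matrix(x[, -1L, drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (min)", ylab = "level (AU)", ...)
  if (!is.null(prot)) graphics::abline(v = switch_times(prot), lty = 3)
  graphics::legend("topright", legend = names(x)[-1L], lty = 1,
                   col = seq_len(ncol(x) - 1L), bty = "n")
  invisible(x)
}

#' Calibrate PHD basal synthesis rates to a steady-state ratio
#'
#' Determines `S1`, `S2`, `S3` of the four-component model so that (i) the
#' normoxic PHD steady states satisfy the prescribed ratio
#' `y1*:y2*:y3* = r1:r2:r3` (0.2:0.8:0.1 by default) and (ii) the normoxic
#' HIF equilibrium equals the anchor `x_ref` (by default the two-component
#' median cell's normoxic equilibrium, about 96.95 AU). The overall PHD scale
#' `Y` follows from the HIF balance
#' \eqn{(x_{ref}/(\gamma+x_{ref})) \sum_i h_i r_i Y = S}, and then
#' \eqn{S_i = d_i r_i Y - k_i x_{ref}}.
#'
#' @param params An [hif_params4()] object (its `S_basal` entries are
#'   replaced).
#' @param target_ratio Positive length-3 vector of relative PHD1:PHD2:PHD3
#'   steady-state protein levels.
#' @param x_ref Normoxic HIF equilibrium anchor, AU; by default the normoxic
#'   equilibrium of a two-component model with the same `S` and `gamma` and
#'   the median-cell `k`, `d` (for the default `S`, `gamma` this is the
#'   median cell's 96.95 AU).
#' @return The calibrated `"hif_params4"` object.
#' @examples
#' wt <- calibrate_basal_synthesis(hif_params4())
#' eq <- hif_equilibrium(wt, 1)
#' eq[c("y1", "y2", "y3")] / sum(eq[c("y1", "y2", "y3")])  # 0.2:0.8:0.1 / 1.1
#' @export
calibrate_basal_synthesis <- function(params,
                                      target_ratio = c(0.2, 0.8, 0.1),
                                      x_ref = NULL) {
  stopifnot(inherits(params, "hif_params4"),
            length(target_ratio) == 3L, all(target_ratio > 0))
  if (is.null(x_ref))
    x_ref <- unname(hif_equilibrium(hif_params(S = params$S,
                                               gamma = params$gamma), 1)["x"])
  stopifnot(is.numeric(x_ref), length(x_ref) == 1L, x_ref > 0)
  Y <- params$S * (params$gamma + x_ref) / x_ref /
    sum(params$h * target_ratio)
  Sb <- params$d * target_ratio * Y - params$k * x_ref
  if (any(Sb < 0))
    stop(sprintf(paste0("infeasible calibration: target ratio incompatible ",
                        "with induction rates (S_%d < 0)"),
                 which(Sb < 0)[1L]))
  params$S_basal <- Sb
  params
}
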