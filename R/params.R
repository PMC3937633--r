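#' Two-component HIF-PHD model parameters
#'
#' Constructs the parameter set of the generic two-component negative-feedback
#' model in which HIF-alpha (`x`, arbitrary fluorescence units, AU) is produced
#' at a constant basal rate and removed by PHD-catalysed (`y`) hydroxylation,
#' while PHD is induced by HIF and degraded at a basal rate:
#' \deqn{dx/dt = S - h y x / (\gamma + x), \quad dy/dt = k x - d y.}
#'
#' The defaults are the median-cell values obtained from free fits to
#' bell-shaped single-cell de-oxygenation traces; they define the "median
#' cell" used as the baseline for sensitivity analysis.
#'
#' @param S HIF basal synthesis rate, AU min^-1. Must be non-negative
#'   (zero only as a degenerate limit).
#' @param gamma Saturation threshold of hydroxylation, AU.
#' @param k HIF-induced PHD production rate, min^-2.
#' @param d PHD basal degradation rate, min^-1.
#' @param h Dimensionless maximal-hydroxylation factor in (0, 1]; 1 in
#'   normoxia, scaled down by the hypoxic ratio (0.14 by default) in hypoxia.
#'   Oxygen protocols multiply this value per segment.
#' @return An object of class `"hif_params"` (a named list).
#' @seealso [hif_params4()], [hif_simulate()], [hif_equilibrium()]
#' @examples
#' p <- hif_params()
#' hif_equilibrium(p, h = 1)
#' @export
hif_params <- function(S = 23.8, gamma = 298, k = 4.71e-4, d = 4.71e-4, h = 1) {
  stopifnot(is.numeric(S), is.numeric(gamma), is.numeric(k), is.numeric(d),
            is.numeric(h), length(S) == 1L, length(gamma) == 1L,
            length(k) == 1L, length(d) == 1L, length(h) == 1L)
  if (!is.finite(S) || S < 0) stop("'S' must be finite and >= 0")
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be finite and > 0")
  if (!is.finite(k) || k <= 0) stop("'k' must be finite and > 0")
  if (!is.finite(d) || d <= 0) stop("'d' must be finite and > 0")
  if (!is.finite(h) || h <= 0 || h > 1) stop("'h' must lie in (0, 1]")
  structure(list(S = S, gamma = gamma, k = k, d = d, h = h),
            class = "hif_params")
}

#' @export
print.hif_params <- function(x, ...) {
  cat("Two-component HIF-PHD model parameters\n")
  cat(sprintf("  S     = %g AU/min (HIF basal synthesis)\n", x$S))
  cat(sprintf("  gamma = %g AU     (hydroxylation saturation)\n", x$gamma))
  cat(sprintf("  k     = %g /min^2 (PHD induction by HIF)\n", x$k))
  cat(sprintf("  d     = %g /min   (PHD basal degradation)\n", x$d))
  cat(sprintf("  h     = %g        (max hydroxylation factor)\n", x$h))
  invisible(x)
}

#' Four-component (isoform-resolved) HIF-PHD model parameters
#'
#' Extends the two-component model to distinguish PHD1 (`y1`), PHD2 (`y2`) and
#' PHD3 (`y3`):
#' \deqn{dx/dt = S - (x/(\gamma+x)) \sum_i h_i y_i,}
#' \deqn{dy_1/dt = S_1 - d_1 y_1,\quad
#'       dy_i/dt = S_i + k_i x - d_i y_i \ (i = 2, 3).}
#' PHD2 and PHD3 are HIF-inducible (rates `k2`, `k3`); PHD1 is not, so its
#' induction rate is identically zero and all three isoforms carry a basal
#' synthesis term. Basal degradation rates are expressed through protein
#' half-lives, \eqn{d_i = \ln 2 / t_{1/2,i}}.
#'
#' Default half-lives are 12 h for PHD1 and PHD2 (measured only as "more than
#' 10 h") and 1.7 h for PHD3; default induction rates equal the two-component
#' median `k` for both inducible isoforms. The basal synthesis rates `S1`-`S3`
#' default to `NA` and are normally filled in by
#' [calibrate_basal_synthesis()], which pins the normoxic steady state to a
#' prescribed PHD1:PHD2:PHD3 ratio.
#'
#' @param S HIF basal synthesis rate, AU min^-1.
#' @param gamma Saturation threshold, AU.
#' @param S1,S2,S3 PHD basal synthesis rates, AU min^-2 scale units;
#'   `NA` until calibrated.
#' @param k2,k3 HIF-induced PHD2/PHD3 production rates, min^-2.
#' @param half_life_h Half-lives of PHD1-3 in hours (length 3); converted to
#'   degradation rates `d_i = log(2)/(60 * half_life_h)`.
#' @param h Per-isoform normoxic hydroxylation rate factors (length 3).
#' @param oxygen_ratio Per-isoform hypoxic/normoxic scaling of `h` applied in
#'   hypoxia (length 3); the measured PHD2 value 0.14 is the default for all
#'   isoforms.
#' @return An object of class `"hif_params4"`.
#' @seealso [calibrate_basal_synthesis()], [knockout_simulation()]
#' @examples
#' wt <- calibrate_basal_synthesis(hif_params4())
#' hif_equilibrium(wt, h = 1)
#' @export
hif_params4 <- function(S = 23.8, gamma = 298,
                        S1 = NA_real_, S2 = NA_real_, S3 = NA_real_,
                        k2 = 4.71e-4, k3 = 4.71e-4,
                        half_life_h = c(12, 12, 1.7),
                        h = c(1, 1, 1),
                        oxygen_ratio = c(0.14, 0.14, 0.14)) {
  stopifnot(length(half_life_h) == 3L, length(h) == 3L,
            length(oxygen_ratio) == 3L)
  if (!is.finite(S) || S < 0) stop("'S' must be finite and >= 0")
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be finite and > 0")
  if (any(!is.finite(half_life_h)) || any(half_life_h <= 0))
    stop("'half_life_h' must be finite and > 0")
  if (!is.finite(k2) || k2 < 0 || !is.finite(k3) || k3 < 0)
    stop("'k2' and 'k3' must be finite and >= 0")
  if (any(!is.finite(h)) || any(h <= 0)) stop("'h' must be finite and > 0")
  if (any(!is.finite(oxygen_ratio)) || any(oxygen_ratio <= 0) ||
      any(oxygen_ratio > 1))
    stop("'oxygen_ratio' must lie in (0, 1]")
  Sb <- c(S1, S2, S3)
  if (any(!is.na(Sb) & Sb < 0)) stop("basal synthesis rates must be >= 0")
  structure(list(S = S, gamma = gamma,
                 S_basal = Sb,
                 k = c(0, k2, k3),
                 d = log(2) / (60 * half_life_h),
                 half_life_h = half_life_h,
                 h = h,
                 oxygen_ratio = oxygen_ratio),
            class = "hif_params4")
}

#' @export
print.hif_params4 <- function(x, ...) {
  cat("Four-component HIF-PHD model parameters (PHD1/2/3)\n")
  cat(sprintf("  S = %g AU/min, gamma = %g AU\n", x$S, x$gamma))
  cat(sprintf("  basal synthesis S_i: %s\n",
              paste(signif(x$S_basal, 4), collapse = ", ")))
  cat(sprintf("  induction k_i:       %s /min^2 (PHD1 not inducible)\n",
              paste(signif(x$k, 4), collapse = ", ")))
  cat(sprintf("  half-lives:          %s h\n",
              paste(x$half_life_h, collapse = ", ")))
  cat(sprintf("  hydroxylation h_i:   %s (hypoxic ratio %s)\n",
              paste(x$h, collapse = ", "),
              paste(x$oxygen_ratio, collapse = ", ")))
  if (anyNA(x$S_basal))
    cat("  [S_i not yet calibrated - see calibrate_basal_synthesis()]\n")
  invisible(x)
}

#' Piecewise-constant oxygen protocol
#'
#' An oxygen protocol is an ordered sequence of contiguous segments, each in a
#' fixed oxygen state (`"normoxia"` or `"hypoxia"`). In normoxia the
#' hydroxylation factor multiplier is 1; in hypoxia it is the hypoxic ratio
#' (0.14 by default, the measured hypoxic/normoxic hydroxylation-rate ratio
#' applied at every 20.8\% to 1\% oxygen switch). Solvers restart at every
#' segment boundary so the discontinuity is never interpolated across.
#'
#' @param start Numeric vector of segment start times, min; must begin at the
#'   protocol start and be strictly increasing.
#' @param state Character vector of oxygen states, one per segment.
#' @param t_end End of the protocol, min.
#' @param hypoxic_ratio Multiplier applied to the hydroxylation factor in
#'   hypoxia, in (0, 1].
#' @return An object of class `"oxygen_protocol"`.
#' @seealso [protocol_deoxygenation()], [protocol_reoxygenation()],
#'   [protocol_constant()]
#' @export
oxygen_protocol <- function(start, state, t_end,
                            hypoxic_ratio = 0.14) {
  stopifnot(length(start) == length(state), length(start) >= 1L,
            is.numeric(start), is.character(state))
  if (any(diff(start) <= 0)) stop("segment start times must be increasing")
  if (!all(state %in% c("normoxia", "hypoxia")))
    stop("oxygen states must be 'normoxia' or 'hypoxia'")
  if (!is.finite(t_end) || t_end <= start[length(start)])
    stop("'t_end' must exceed the last segment start")
  if (!is.finite(hypoxic_ratio) || hypoxic_ratio <= 0 || hypoxic_ratio > 1)
    stop("'hypoxic_ratio' must lie in (0, 1]")
  structure(list(start = as.numeric(start), state = state,
                 t_end = as.numeric(t_end),
                 hypoxic_ratio = hypoxic_ratio),
            class = "oxygen_protocol")
}

#' De-oxygenation protocol: normoxic baseline, then continuous hypoxia
#'
#' The standard imaging protocol: cells observed every few minutes in 20.8\%
#' oxygen for a baseline hour, then switched to 1\% oxygen for 20 h.
#'
#' @param baseline_min Normoxic baseline duration, min.
#' @param hypoxia_min Hypoxic duration after the switch, min.
#' @param hypoxic_ratio Hypoxic hydroxylation multiplier.
#' @return An `"oxygen_protocol"`.
#' @export
protocol_deoxygenation <- function(baseline_min = 60, hypoxia_min = 1200,
                                   hypoxic_ratio = 0.14) {
  oxygen_protocol(c(0, baseline_min), c("normoxia", "hypoxia"),
                  t_end = baseline_min + hypoxia_min,
                  hypoxic_ratio = hypoxic_ratio)
}

#' Re-oxygenation protocol: hypoxia, then return to normoxia
#'
#' Emulates the re-oxygenation experiment: cells exposed to 1\% oxygen for
#' 6 h and then returned to 20.8\% oxygen.
#'
#' @param hypoxia_min Hypoxic duration before the switch, min.
#' @param normoxia_min Normoxic duration after the switch, min.
#' @param hypoxic_ratio Hypoxic hydroxylation multiplier.
#' @return An `"oxygen_protocol"`.
#' @export
protocol_reoxygenation <- function(hypoxia_min = 360, normoxia_min = 360,
                                   hypoxic_ratio = 0.14) {
  oxygen_protocol(c(0, hypoxia_min), c("hypoxia", "normoxia"),
                  t_end = hypoxia_min + normoxia_min,
                  hypoxic_ratio = hypoxic_ratio)
}

#' Constant-oxygen protocol
#'
#' @param state `"normoxia"` or `"hypoxia"`.
#' @param duration_min Protocol duration, min.
#' @param hypoxic_ratio Hypoxic hydroxylation multiplier.
#' @return An `"oxygen_protocol"`.
#' @export
protocol_constant <- function(state = "normoxia", duration_min = 1260,
                              hypoxic_ratio = 0.14) {
  oxygen_protocol(0, state, t_end = duration_min,
                  hypoxic_ratio = hypoxic_ratio)
}

#' @export
print.oxygen_protocol <- function(x, ...) {
  cat("Oxygen protocol (hypoxic ratio", x$hypoxic_ratio, ")\n")
  ends <- c(x$start[-1L], x$t_end)
  for (i in seq_along(x$start))
    cat(sprintf("  [%g, %g] min: %s (h multiplier %g)\n",
                x$start[i], ends[i], x$state[i],
                if (x$state[i] == "hypoxia") x$hypoxic_ratio else 1))
  invisible(x)
}

#' Hydroxylation multiplier of a protocol at given times
#'
#' @param protocol An `"oxygen_protocol"`.
#' @param t Times, min.
#' @return Numeric vector of multipliers (1 in normoxia, the hypoxic ratio in
#'   hypoxia). Times outside the protocol take the nearest segment's value.
#' @export
protocol_multiplier <- function(protocol, t) {
  stopifnot(inherits(protocol, "oxygen_protocol"))
  seg <- findInterval(t, protocol$start, rightmost.closed = FALSE)
  seg[seg < 1L] <- 1L
  ifelse(protocol$state[seg] == "hypoxia", protocol$hypoxic_ratio, 1)
}

#' Switch times of a protocol
#'
#' @param protocol An `"oxygen_protocol"`.
#' @return Numeric vector of internal segment boundaries (possibly empty).
#' @export
switch_times <- function(protocol) {
  stopifnot(inherits(protocol, "oxygen_protocol"))
  protocol$start[-1L]
}
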