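# shared fixtures, built in code

# the median cell (free-fit medians over bell-shaped de-oxygenation traces)
med <- hif_params()
med_true <- c(S = 23.8, gamma = 298, k = 4.71e-4, d = 4.71e-4)

# independent oracle for the two-component equilibrium: positive root of
# h (k/d) x^2 - S x - S gamma = 0 obtained with polyroot(), not the
# closed form used by the package
equilibrium_oracle <- function(p, h_mult = 1) {
  a <- p$h * h_mult * p$k / p$d
  r <- polyroot(c(-p$S * p$gamma, -p$S, a))
  x <- Re(r[abs(Im(r)) < 1e-9 & Re(r) > 0])
  c(x = x, y = p$k * x / p$d)
}

# noiseless median-cell de-oxygenation trace sampled like the experiments
# (every 5 min, 1 h normoxia + 20 h hypoxia)
median_trace <- local({
  tr <- hif_simulate(med, protocol_deoxygenation(), times = seq(0, 1260, 5))
  data.frame(time = tr$time, value = tr$x)
})

# piecewise-linear pulse on a 5-min grid: baseline `base`, rising to
# `base + amp` at t_peak, back down at t_peak + half-width
linear_pulse <- function(t, t_on, t_peak, t_off, base = 100, amp = 400) {
  up <- (t - t_on) / (t_peak - t_on)
  down <- (t_off - t) / (t_off - t_peak)
  base + amp * pmax(0, pmin(up, down, 1))
}
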