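# Shared fixtures built in code.

# An sta-class object holding a planted separable kernel: elliptical
# Gaussian (sds in px) x difference-of-cascades time course.
planted_sta <- function(p1 = 1, p2 = 0.8, tau1 = 4, tau2 = 6, n = 6,
                        n_lags = 18, grid = 40, sx = 5, sy = 5,
                        x0 = 20, y0 = 20, sign = 1, px_per_mm = 100,
                        frame_dt = 1 / 60) {
  tk <- rgcspeed:::temporal_kernel(seq_len(n_lags) - 1, p1, p2, tau1, tau2, n)
  xs <- seq_len(grid)
  sp <- sign * exp(-0.5 * (outer((xs - y0)^2 / sy^2, (xs - x0)^2 / sx^2, "+")))
  kernel <- array(0, dim = c(n_lags, grid, grid))
  for (j in seq_len(n_lags)) kernel[j, , ] <- tk[j] * sp
  rgcspeed:::new_sta(kernel, frame_dt, 1000, px_per_mm)
}

# One-cell population with fixed geometry for simulator-based tests.
fixed_cell <- function(gain = 250, baseline = 0.5, field = 1.2,
                       tau1 = 4, tau2 = 6.5, p2 = 0.6, radius = 0.1,
                       polarity = "OFF") {
  pop <- make_ground_truth_population(1, on_fraction = 0,
                                      rf_radius_mean = radius,
                                      rf_radius_sd = 1e-9,
                                      field_size = field,
                                      baseline_rate_range = c(baseline, baseline),
                                      gain_range = c(gain, gain),
                                      tau1_range = c(tau1, tau1),
                                      tau2_range = c(tau2, tau2),
                                      p2_range = c(p2, p2), seed = 99)
  pop$x <- field / 2; pop$y <- field / 2
  pop$polarity <- polarity
  pop
}

# psth object from a rate vector (for spectrum-level tests).
psth_from_rates <- function(rates, bin_width = 0.05, onset = 0.2) {
  edges <- onset + seq(0, length(rates)) * bin_width
  structure(list(bin_edges = edges, mids = edges[-length(edges)] + bin_width / 2,
                 rates = rates, n_trials = 1, onset_discard = onset,
                 bin_width = bin_width),
            class = "psth")
}
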