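# Ground-truth linear-nonlinear Poisson retina used in place of recordings.

#' Generate a ground-truth ganglion-cell population
#'
#' Cells have elliptical Gaussian spatial receptive fields (equivalent radius
#' `sqrt(a*b)` drawn from a truncated normal), biphasic difference-of-cascades
#' temporal kernels, a half-wave rectifying output nonlinearity with additive
#' baseline, and ON/OFF polarity implemented as a kernel sign flip. The ON
#' fraction defaults to 0.2, reflecting the low ON/OFF ratio typical of the
#' recorded retinas this simulator emulates.
#'
#' @param n_cells number of cells.
#' @param on_fraction proportion of ON cells in `[0, 1]`; exactly
#'   `round(n_cells * on_fraction)` cells are ON.
#' @param rf_radius_mean,rf_radius_sd equivalent-radius distribution, mm.
#' @param field_size side of the square field the centres tile, mm.
#' @param baseline_rate_range,gain_range per-cell uniform ranges (Hz and
#'   Hz per unit filtered contrast).
#' @param tau1_range,tau2_range,p2_range,n_cascade temporal-kernel parameter
#'   ranges: cascade peak times in frames (> 1) and second-lobe amplitude.
#' @param seed integer RNG seed.
#' @return data.frame of class `rgc_population`, one row per cell, columns
#'   `cell_id, x, y, a, b, angle, polarity, p1, p2, tau1, tau2, n_cascade,
#'   baseline_rate, gain`.
#' @export
make_ground_truth_population <- function(n_cells, on_fraction = 0.2,
                                         rf_radius_mean = 0.10,
                                         rf_radius_sd = 0.02,
                                         field_size = 1.75,
                                         baseline_rate_range = c(0.5, 2),
                                         gain_range = c(20, 60),
                                         tau1_range = c(3, 5),
                                         tau2_range = c(6, 9),
                                         p2_range = c(0.4, 0.8),
                                         n_cascade = 6,
                                         seed = NULL) {
  stopifnot_positive(n_cells = n_cells, field_size = field_size,
                     rf_radius_mean = rf_radius_mean)
  if (on_fraction < 0 || on_fraction > 1) {
    stop("invalid parameter: `on_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n_on <- round(n_cells * on_fraction)
  with_seed(seed, {
    r <- stats::rnorm(n_cells, rf_radius_mean, rf_radius_sd)
    r <- pmax(r, rf_radius_mean / 10)
    q <- stats::runif(n_cells, 0.6, 1)       # (b/a)^... aspect ratio b/a
    a <- r / sqrt(q)
    b <- r * sqrt(q)
    pol <- rep("OFF", n_cells)
    if (n_on > 0) pol[sample.int(n_cells, n_on)] <- "ON"
    pop <- data.frame(
      cell_id = seq_len(n_cells),
      x = stats::runif(n_cells, 0, field_size),
      y = stats::runif(n_cells, 0, field_size),
      a = a, b = b,
      angle = stats::runif(n_cells, 0, pi),
      polarity = pol,
      p1 = 1,
      p2 = stats::runif(n_cells, p2_range[1], p2_range[2]),
      tau1 = stats::runif(n_cells, tau1_range[1], tau1_range[2]),
      tau2 = stats::runif(n_cells, tau2_range[1], tau2_range[2]),
      n_cascade = n_cascade,
      baseline_rate = stats::runif(n_cells, baseline_rate_range[1],
                                   baseline_rate_range[2]),
      gain = stats::runif(n_cells, gain_range[1], gain_range[2]),
      stringsAsFactors = FALSE)
    class(pop) <- c("rgc_population", "data.frame")
    attr(pop, "field_size") <- field_size
    pop
  })
}

#' Attach skewed log-Gaussian speed-tuning parameters to a population
#'
#' Gives each cell the parameters of a skewed log-Gaussian speed-tuning
#' curve: peak rate `A` (Hz), preferred speed `V` (mm/s), width `sigma_v`
#' (log2-speed units) and skew `zeta`.
#'
#' @param population an `rgc_population`.
#' @param A_range,V_range,sigma_v_range,zeta_range uniform sampling ranges
#'   (`V` sampled log-uniformly).
#' @param seed integer RNG seed.
#' @return the population with columns `A, V, sigma_v, zeta` added.
#' @export
attach_speed_tuning <- function(population, A_range = c(10, 30),
                                V_range = c(0.5, 2), sigma_v_range = c(1, 2),
                                zeta_range = c(-0.2, 0.2), seed = NULL) {
  n <- nrow(population)
  with_seed(seed, {
    population$A <- stats::runif(n, A_range[1], A_range[2])
    population$V <- 2^stats::runif(n, log2(V_range[1]), log2(V_range[2]))
    population$sigma_v <- stats::runif(n, sigma_v_range[1], sigma_v_range[2])
    population$zeta <- stats::runif(n, zeta_range[1], zeta_range[2])
    population
  })
}

# Low-pass cascade, peaks at t = tau with unit amplitude; t in frames.
cascade_filter <- function(t, tau, n) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tau)^n * exp(-n * (t[pos] / tau - 1))
  out
}

# Biphasic temporal kernel: difference of two cascades with shared order.
temporal_kernel <- function(t, p1, p2, tau1, tau2, n) {
  p1 * cascade_filter(t, tau1, n) - p2 * cascade_filter(t, tau2, n)
}

# Spatial receptive-field map of one cell on a movie's pixel grid.
# Returns [y, x] matrix with unit L2 norm, signed by polarity (so `gain`
# is Hz per unit of filtered contrast along the kernel direction).
cell_spatial_map <- function(cell, n_y, n_x, px_per_mm) {
  px <- seq_len(n_x) / px_per_mm           # mm
  py <- seq_len(n_y) / px_per_mm
  ca <- cos(cell$angle); sa <- sin(cell$angle)
  dx <- outer(rep(1, n_y), px - cell$x)
  dy <- outer(py - cell$y, rep(1, n_x))
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  m <- exp(-0.5 * ((u / cell$a)^2 + (v / cell$b)^2))
  s <- sqrt(sum(m^2))
  if (s == 0) return(m)
  sign <- if (identical(cell$polarity, "ON")) 1 else -1
  sign * m / s
}

# Full separable spatiotemporal kernel as an `sta`-like object (lag, y, x);
# lag 1 = 0 frames before the spike. Used as the planted ground truth.
#' Ground-truth spatiotemporal kernel of one simulated cell
#'
#' Builds the separable kernel (temporal cascade x elliptical Gaussian) that
#' the linear-nonlinear simulator uses for a cell, on the pixel grid of a
#' movie geometry, packaged like a spike-triggered average so it can be fed
#' to the same fitting and collapsing routines.
#'
#' @param cell one-row slice of an `rgc_population`.
#' @param n_y,n_x grid size, pixels.
#' @param px_per_mm calibration.
#' @param frame_dt frame duration, s.
#' @param n_lags kernel depth, frames.
#' @return an object of class `sta`.
#' @export
ground_truth_kernel <- function(cell, n_y, n_x, px_per_mm, frame_dt = 1 / 60,
                                n_lags = 18) {
  sp <- cell_spatial_map(cell, n_y, n_x, px_per_mm)
  tk <- temporal_kernel(seq_len(n_lags) - 1, cell$p1, cell$p2,
                        cell$tau1, cell$tau2, cell$n_cascade)
  kernel <- array(0, dim = c(n_lags, n_y, n_x))
  for (j in seq_len(n_lags)) kernel[j, , ] <- tk[j] * sp
  new_sta(kernel, frame_dt = frame_dt, n_spikes = NA_integer_,
          px_per_mm = px_per_mm)
}

spike_data_frame <- function(cell_id, kind, sf0, speed, trial, spike_time_s) {
  n <- length(spike_time_s)
  data.frame(cell_id = rep_len(cell_id, n), kind = rep_len(kind, n),
             sf0 = rep_len(sf0, n), speed = rep_len(speed, n),
             trial = rep_len(trial, n), spike_time_s = spike_time_s,
             stringsAsFactors = FALSE)
}

as_spike_data <- function(df, duration, n_trials, seed = NULL) {
  df <- df[order(df$cell_id, df$kind, df$sf0, df$speed, df$trial,
                 df$spike_time_s), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, duration = duration, n_trials = n_trials, seed = seed,
            class = c("spike_data", "data.frame"))
}

# Draw spike times from per-bin Poisson counts; times uniform within bins.
draw_spikes_from_rate <- function(rate_hz, bin_dt, deterministic = FALSE) {
  lam <- pmax(rate_hz, 0) * bin_dt
  counts <- if (deterministic) round(lam) else stats::rpois(length(lam), lam)
  if (sum(counts) == 0) return(numeric(0))
  bins <- rep(seq_along(counts) - 1, counts)
  sort(bins * bin_dt + stats::runif(length(bins)) * bin_dt)
}

#' Simulate linear-nonlinear Poisson responses to a movie
#'
#' Each cell's drive is the spatiotemporal inner product of its separable
#' kernel with the mean-subtracted movie; the firing rate is
#' `baseline + gain * max(0, drive)` per frame, and per-bin spike counts are
#' Poisson (independent across trials). Seeded runs are reproducible.
#'
#' @param population an `rgc_population`.
#' @param movie a `stimulus_movie` whose calibration matches the population
#'   field units.
#' @param n_trials repetitions.
#' @param bin_dt rate-evaluation bin, s (default one stimulus frame).
#' @param n_lags temporal kernel depth, frames.
#' @param seed integer RNG seed.
#' @param deterministic if `TRUE`, per-bin counts are `round(rate * dt)`
#'   instead of Poisson draws (noiseless-rate mode for closed-loop checks).
#' @param gain_scale global multiplier on all cell gains.
#' @return a `spike_data` data.frame (columns `cell_id, kind, sf0, speed,
#'   trial, spike_time_s`) with `duration` and `n_trials` attributes.
#' @export
simulate_ln_responses <- function(population, movie, n_trials = 1,
                                  bin_dt = NULL, n_lags = 18, seed = NULL,
                                  deterministic = FALSE, gain_scale = 1) {
  stopifnot(inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  bin_dt <- bin_dt %||% (1 / movie$frame_rate)
  frames_mat <- matrix(movie$frames, nrow = d[1])   # [time, y*x]
  frames_mat <- frames_mat - mean(frames_mat)
  with_seed(seed, {
    out <- vector("list", nrow(population) * n_trials)
    k <- 0L
    for (i in seq_len(nrow(population))) {
      cell <- population[i, ]
      sp <- cell_spatial_map(cell, d[2], d[3], movie$px_per_mm)
      drive_sp <- as.numeric(frames_mat %*% as.numeric(sp))
      tk <- temporal_kernel(seq_len(n_lags) - 1, cell$p1, cell$p2,
                            cell$tau1, cell$tau2, cell$n_cascade)
      g <- as.numeric(stats::filter(drive_sp, tk, method = "convolution",
                                    sides = 1))
      g[is.na(g)] <- 0
      rate <- cell$baseline_rate + gain_scale * cell$gain * pmax(g, 0)
      stopifnot(all(rate >= 0))
      # resample the per-frame rate onto the requested bin grid
      if (abs(bin_dt - 1 / movie$frame_rate) > 1e-12) {
        tt <- (seq_len(round(movie$duration / bin_dt)) - 0.5) * bin_dt
        idx <- pmin(pmax(ceiling(tt * movie$frame_rate), 1), length(rate))
        rate <- rate[idx]
      }
      for (tr in seq_len(n_trials)) {
        st <- draw_spikes_from_rate(rate, bin_dt, deterministic)
        k <- k + 1L
        out[[k]] <- spike_data_frame(cell$cell_id, movie$kind, movie$sf0,
                                     movie$speed, tr, st)
      }
    }
    as_spike_data(do.call(rbind, out), movie$duration, n_trials, seed)
  })
}

#' Skewed log-Gaussian speed-tuning curve
#'
#' `R(v) = A * (exp(-(log2 v - log2 V)^2 / (2 * (sigma_v + zeta*(log2 v -
#' log2 V))^2)) - exp(-1/zeta^2))`, clamped at 0. The maximum over `v > 0`
#' is at `v = V` with value `A * (1 - exp(-1/zeta^2))`.
#'
#' @param v speeds, mm/s (> 0).
#' @param A scale, Hz. @param V preferred speed, mm/s.
#' @param sigma_v width, log2-speed units (> 0). @param zeta skew.
#' @return firing rates, Hz.
#' @export
speed_tuning_curve <- function(v, A, V, sigma_v, zeta) {
  stopifnot_positive(V = V, sigma_v = sigma_v)
  stopifnot_positive(v = v)
  u <- log2(v) - log2(V)
  denom <- sigma_v + zeta * u
  if (any(denom <= 0)) {
    stop("invalid parameter: skew makes the width term non-positive over ",
         "the requested speed range", call. = FALSE)
  }
  floor_term <- if (zeta == 0) 0 else exp(-1 / zeta^2)
  pmax(A * (exp(-u^2 / (2 * denom^2)) - floor_term), 0)
}

#' Simulate speed-tuned spike trains over a condition grid
#'
#' For each (cell, condition, trial), spikes are Poisson with mean rate
#' given by the cell's skewed log-Gaussian tuning curve evaluated at the
#' condition speed. `sigma_scale` multiplies each cell's `sigma_v` per
#' stimulus class, emulating bandwidth-dependent tuning narrowing in
#' end-to-end demonstrations. With `f1_modulation = 0` (default) spiking is
#' homogeneous within a condition; a positive value superimposes sinusoidal
#' rate modulation at the condition's grating temporal frequency
#' (`sf0 * speed`), giving the periodic response structure that the
#' modulation screen measures.
#'
#' @param population an `rgc_population` with tuning columns (see
#'   [attach_speed_tuning()]).
#' @param conditions data.frame with columns `kind, sf0, speed` (see
#'   [condition_grid()]).
#' @param duration trial length, s.
#' @param n_trials repetitions per condition.
#' @param sigma_scale named numeric, multiplier of `sigma_v` per kind.
#' @param f1_modulation relative amplitude in `[0, 1]` of sinusoidal rate
#'   modulation at the stimulus temporal frequency.
#' @param bin_dt rate bin for the modulated generator, s.
#' @param seed integer RNG seed.
#' @return a `spike_data` data.frame.
#' @export
simulate_tuned_spike_trains <- function(population, conditions, duration = 3,
                                        n_trials = 10,
                                        sigma_scale = c(grating = 1,
                                                        mc_narrow = 0.82,
                                                        mc_broad = 0.54),
                                        f1_modulation = 0, bin_dt = 1 / 60,
                                        seed = NULL) {
  stopifnot(all(c("A", "V", "sigma_v", "zeta") %in% names(population)))
  stopifnot(all(c("kind", "sf0", "speed") %in% names(conditions)))
  n_bins <- round(duration / bin_dt)
  tt <- (seq_len(n_bins) - 0.5) * bin_dt
  with_seed(seed, {
    out <- vector("list", nrow(population) * nrow(conditions))
    k <- 0L
    for (i in seq_len(nrow(population))) {
      cell <- population[i, ]
      for (ci in seq_len(nrow(conditions))) {
        cond <- conditions[ci, ]
        sc <- sigma_scale[[cond$kind]] %||% 1
        r0 <- speed_tuning_curve(cond$speed, cell$A, cell$V,
                                 cell$sigma_v * sc, cell$zeta)
        if (f1_modulation > 0) {
          tf <- cond$sf0 * cond$speed
          rate <- r0 * (1 + f1_modulation * sin(2 * pi * tf * tt))
          st_list <- lapply(seq_len(n_trials), function(tr)
            draw_spikes_from_rate(rate, bin_dt))
        } else {
          # homogeneous within the trial: draw total counts directly
          ns <- stats::rpois(n_trials, r0 * duration)
          st_list <- lapply(ns, function(m) sort(stats::runif(m, 0, duration)))
        }
        ntr <- rep(seq_len(n_trials), lengths(st_list))
        k <- k + 1L
        out[[k]] <- spike_data_frame(cell$cell_id, cond$kind, cond$sf0,
                                     cond$speed, ntr, unlist(st_list))
      }
    }
    as_spike_data(do.call(rbind, out), duration, n_trials, seed)
  })
}

#' Chunked spike-triggered average of a simulated checkerboard run
#'
#' Simulates a long white-noise checkerboard response of one cell in seeded
#' chunks (keeping memory bounded) and merges the per-chunk
#' spike-triggered averages by the exact spike-count-weighted identity.
#' Returns the merged STA together with the planted kernel for recovery
#' checks.
#'
#' @param cell a one-row `rgc_population` slice.
#' @param total_duration total run length, s.
#' @param chunk_s chunk length, s.
#' @param block_size_mm,n_blocks,frame_rate checkerboard geometry.
#' @param n_lags STA depth, frames.
#' @param gain_scale global gain multiplier.
#' @param seed master seed; each chunk derives its own.
#' @return list: `sta` (merged), `planted` (`sta` object of the true
#'   kernel), `n_spikes`.
#' @export
sta_checkerboard_run <- function(cell, total_duration = 1200, chunk_s = 60,
                                 block_size_mm = 0.05, n_blocks = 24,
                                 frame_rate = 60, n_lags = 15,
                                 gain_scale = 1, seed = 1) {
  n_chunks <- ceiling(total_duration / chunk_s)
  stas <- list()
  for (ch in seq_len(n_chunks)) {
    cb <- make_checkerboard(block_size_mm, n_blocks, chunk_s, frame_rate,
                            seed = derive_seed(seed + ch, "stimuli"))
    spk <- simulate_ln_responses(cell, cb, n_trials = 1,
                                 seed = derive_seed(seed + ch, "responses"),
                                 n_lags = n_lags, gain_scale = gain_scale)
    st <- spk$spike_time_s
    if (length(st) == 0) next
    stas[[length(stas) + 1]] <- tryCatch(compute_sta(st, cb, n_lags),
                                         error = function(e) NULL)
  }
  stas <- Filter(Negate(is.null), stas)
  if (length(stas) == 0) stop("no spikes in the whole run", call. = FALSE)
  sta <- combine_sta(stas)
  planted <- ground_truth_kernel(cell, n_blocks, n_blocks,
                                 1 / block_size_mm, 1 / frame_rate, n_lags)
  list(sta = sta, planted = planted, n_spikes = sta$n_spikes)
}

#' Extract spike times for one cell/condition from a spike table
#'
#' @param spikes a `spike_data` data.frame.
#' @param cell_id,kind,sf0,speed optional filters.
#' @param by_trial if `TRUE`, return a list of per-trial numeric vectors
#'   (every trial present, possibly empty); otherwise one pooled vector.
#' @return numeric vector or list of numeric vectors of spike times, s.
#' @export
spike_times <- function(spikes, cell_id = NULL, kind = NULL, sf0 = NULL,
                        speed = NULL, by_trial = FALSE) {
  sel <- rep(TRUE, nrow(spikes))
  if (!is.null(cell_id)) sel <- sel & spikes$cell_id %in% cell_id
  if (!is.null(kind)) sel <- sel & spikes$kind %in% kind
  if (!is.null(sf0)) sel <- sel & abs(spikes$sf0 - sf0) < 1e-9
  if (!is.null(speed)) sel <- sel & abs(spikes$speed - speed) < 1e-9
  sub <- spikes[sel, , drop = FALSE]
  if (!by_trial) return(sort(sub$spike_time_s))
  n_trials <- attr(spikes, "n_trials") %||% max(c(1, sub$trial))
  lapply(seq_len(n_trials), function(tr) sort(sub$spike_time_s[sub$trial == tr]))
}
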