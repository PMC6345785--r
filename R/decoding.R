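# Stimulus reconstruction from population spikes and motion-energy speed
# decoding (Reichardt-style quadrature filters, opponent subtraction,
# winner-takes-all).

#' Collapse a spatiotemporal receptive field to space-time
#'
#' Averages the 3-D kernel over the axis orthogonal to motion (image rows),
#' using the unweighted mean across the rows intersecting the receptive
#' field's 2-standard-deviation vertical extent (estimated from the row
#' energy profile at the peak lag). Separable kernels keep their separable
#' structure and the collapse is invariant to translations along the
#' orthogonal axis.
#'
#' @param sta an `sta` object.
#' @return list of class `collapsed_rf`: `rf` (matrix space x lag),
#'   `rows` used, `frame_dt`, `px_per_mm`.
#' @export
collapse_rf <- function(sta) {
  stopifnot(inherits(sta, "sta"))
  k <- sta$kernel
  peak_lag <- which.max(apply(abs(k), 1, max))
  m <- k[peak_lag, , ]
  e <- rowSums(m^2)
  ys <- seq_along(e)
  if (sum(e) == 0) {
    rows <- ys
  } else {
    mu <- sum(e * ys) / sum(e)
    sd_ <- sqrt(max(sum(e * (ys - mu)^2) / sum(e), 0.25))
    rows <- ys[abs(ys - mu) <= 2 * sd_]
    if (length(rows) == 0) rows <- round(mu)
  }
  L <- dim(k)[1]
  rf <- vapply(seq_len(L), function(j) {
    slice <- k[j, rows, , drop = FALSE]          # 1 x n_rows x n_x
    colMeans(matrix(slice, nrow = length(rows)))
  }, numeric(dim(k)[3]))                         # rf is [x, lag]
  structure(list(rf = rf, rows = rows, frame_dt = sta$frame_dt,
                 px_per_mm = sta$px_per_mm),
            class = "collapsed_rf")
}

#' Linear space-time reconstruction from spike trains
#'
#' Evaluates `I(x, i) = a + sum_c w_c sum_j r^c_(i-j) RF^c(x, j)` with spike
#' counts `r` binned at `bin_dt` (default one frame, 1/60 s). With no
#' spikes the reconstruction equals the offset everywhere, and it is linear
#' in the spike counts.
#'
#' @param spikes a `spike_data` slice (one condition; trials pooled unless
#'   `trial` is given) or a named list of spike-time vectors per cell.
#' @param kernels named list of `collapsed_rf` objects keyed by cell id;
#'   every cell present in `spikes` must have a kernel.
#' @param duration reconstruction length, s.
#' @param weights per-cell weights, recycled (default 1; the readout has no
#'   access to the true signal, so no weight fitting is performed).
#' @param offset constant `a` (default 0; use the stimulus mean to place
#'   the reconstruction on the luminance scale).
#' @param bin_dt s.
#' @param trial optional trial number to select.
#' @return list of class `xt_reconstruction`: `intensity` (space x time
#'   matrix), `x_mm`, `bin_dt`, `offset`.
#' @export
reconstruct_xt <- function(spikes, kernels, duration, weights = 1,
                           offset = 0, bin_dt = 1 / 60, trial = NULL) {
  stopifnot_positive(bin_dt = bin_dt, duration = duration)
  if (is.data.frame(spikes)) {
    if (!is.null(trial)) spikes <- spikes[spikes$trial == trial, , drop = FALSE]
    ids <- as.character(sort(unique(spikes$cell_id)))
    spk <- lapply(ids, function(id)
      spikes$spike_time_s[as.character(spikes$cell_id) == id])
    names(spk) <- ids
  } else {
    spk <- spikes
    ids <- names(spk)
  }
  missing_k <- setdiff(ids, names(kernels))
  if (length(missing_k) > 0) {
    stop("missing kernel for cell(s): ", paste(missing_k, collapse = ", "),
         call. = FALSE)
  }
  n_bins <- round(duration / bin_dt)
  weights <- rep_len(weights, length(ids))
  nx <- nrow(kernels[[1]]$rf)
  I <- matrix(offset, nrow = nx, ncol = n_bins)
  edges <- seq(0, n_bins) * bin_dt
  for (ci in seq_along(ids)) {
    rf <- kernels[[ids[ci]]]$rf
    st <- spk[[ci]]
    st <- st[st >= 0 & st < duration]
    if (length(st) == 0) next
    r <- tabulate(findInterval(st, edges, rightmost.closed = FALSE),
                  nbins = n_bins)
    L <- ncol(rf)
    for (j in seq_len(L)) {
      idx <- j:n_bins
      I[, idx] <- I[, idx] +
        weights[ci] * outer(rf[, j], r[seq_len(n_bins - j + 1)])
    }
  }
  ppm <- kernels[[1]]$px_per_mm %||% NA_real_
  structure(list(intensity = I,
                 x_mm = if (is.na(ppm)) seq_len(nx) else seq_len(nx) / ppm,
                 bin_dt = bin_dt, offset = offset),
            class = "xt_reconstruction")
}

# Valid-region 2-D cross-correlation via FFT; X and K are matrices,
# dim(K) <= dim(X). Result[dy+1, dx+1] = sum X[y+dy, x+dx] K[y, x].
xcorr2_valid <- function(X, K) {
  nrX <- nrow(X); ncX <- ncol(X); nrK <- nrow(K); ncK <- ncol(K)
  stopifnot(nrK <= nrX, ncK <= ncX)
  nr <- nrX + nrK - 1; nc <- ncX + ncK - 1
  Xp <- matrix(0, nr, nc); Xp[1:nrX, 1:ncX] <- X
  Kp <- matrix(0, nr, nc); Kp[1:nrK, 1:ncK] <- K
  C <- Re(stats::fft(stats::fft(Xp) * Conj(stats::fft(Kp)), inverse = TRUE)) /
    (nr * nc)
  C[1:(nrX - nrK + 1), 1:(ncX - ncK + 1), drop = FALSE]
}

#' Build a quadrature motion-energy filter bank
#'
#' One channel per candidate speed and direction: a quadrature pair of
#' space-time slanted Gabor kernels whose carrier translates at the
#' preferred speed (the speed tuning is the slant angle in the space-time
#' plane). Kernels are zero-mean and unit-energy; the two pair members
#' differ in carrier phase by 90 degrees, and mirror-reversing a kernel in
#' space gives the opposite-direction kernel.
#'
#' @param speeds candidate speeds, mm/s (> 0, distinct).
#' @param sf carrier spatial frequency, cycles/mm.
#' @param px_per_mm,frame_rate grid calibration of the images to be
#'   filtered.
#' @param sigma_x_mm spatial envelope s.d., mm (default `1/(2*sf)`).
#' @param n_periods temporal half-extent target in carrier periods.
#' @param t_max_s cap on each channel's temporal half-extent, s. The
#'   2-period rule exceeds short trials for slow channels; the default cap
#'   of 1 s keeps a valid correlation window of at least a third of a 3-s
#'   trial, which the slow channels need to estimate slant reliably.
#' @return list of class `motion_energy_bank`; per channel `even`, `odd`
#'   kernel matrices (space x time) for each direction.
#' @export
build_motion_energy_bank <- function(speeds, sf, px_per_mm = 240,
                                     frame_rate = 60, sigma_x_mm = NULL,
                                     n_periods = 2, t_max_s = 1) {
  stopifnot_positive(sf = sf, px_per_mm = px_per_mm, frame_rate = frame_rate)
  stopifnot_positive(speeds = speeds)
  if (anyDuplicated(speeds)) stop("candidate speeds must be distinct",
                                  call. = FALSE)
  sigma_x_mm <- sigma_x_mm %||% (1 / (2 * sf))
  channels <- list()
  for (v in speeds) {
    half_t <- min(n_periods / (sf * v), t_max_s)
    ht <- max(round(half_t * frame_rate), 2)
    hx <- max(round(2.5 * sigma_x_mm * px_per_mm), 2)
    x_mm <- (seq(-hx, hx)) / px_per_mm
    t_s <- (seq(-ht, ht)) / frame_rate
    envx <- exp(-x_mm^2 / (2 * sigma_x_mm^2))
    sigma_t <- half_t / 2
    envt <- exp(-t_s^2 / (2 * sigma_t^2))
    env <- outer(envx, envt)
    dirs <- list()
    for (d in c(1, -1)) {
      ph <- 2 * pi * sf * outer(x_mm, -d * v * t_s, "+")
      even <- env * cos(ph)
      odd <- env * sin(ph)
      even <- even - mean(even)
      odd <- odd - mean(odd)
      even <- even / sqrt(sum(even^2))
      odd <- odd / sqrt(sum(odd^2))
      dirs[[if (d == 1) "fwd" else "bwd"]] <- list(even = even, odd = odd)
    }
    channels[[length(channels) + 1]] <- list(speed = v, fwd = dirs$fwd,
                                             bwd = dirs$bwd)
  }
  structure(list(channels = channels, sf = sf, px_per_mm = px_per_mm,
                 frame_rate = frame_rate),
            class = "motion_energy_bank")
}

#' Decode speed from a space-time image by opponent motion energy
#'
#' Each channel's motion energy is the mean over valid filter positions of
#' the summed squared quadrature outputs (squaring makes the energy phase
#' invariant); the net motion signal is forward minus backward energy, and
#' the winner-takes-all readout picks the channel with the highest net
#' signal. A static pattern has mirror-equal energies in both directions,
#' so all net signals vanish and a no-decision flag is returned instead of
#' an arbitrary choice.
#'
#' @param xt an `xt_reconstruction`, or a space x time matrix.
#' @param bank a `motion_energy_bank`; kernels must fit inside the image.
#' @param no_decision_tol net-to-total energy ratio under which no decision
#'   is declared.
#' @return list: `speeds`, `net`, `energy_fwd`, `energy_bwd`,
#'   `chosen_speed` (`NA` on no-decision), `no_decision`.
#' @export
decode_speed <- function(xt, bank, no_decision_tol = 1e-6) {
  stopifnot(inherits(bank, "motion_energy_bank"))
  X <- if (inherits(xt, "xt_reconstruction")) xt$intensity else xt
  X <- X - mean(X)
  nsp <- length(bank$channels)
  net <- e_fwd <- e_bwd <- numeric(nsp)
  speeds <- vapply(bank$channels, `[[`, numeric(1), "speed")
  for (i in seq_len(nsp)) {
    ch <- bank$channels[[i]]
    if (nrow(ch$fwd$even) > nrow(X) || ncol(ch$fwd$even) > ncol(X)) {
      stop("kernel extent exceeds the image grid (channel speed ",
           ch$speed, " mm/s)", call. = FALSE)
    }
    energy <- function(pair) {
      ce <- xcorr2_valid(X, pair$even)
      co <- xcorr2_valid(X, pair$odd)
      mean(ce^2 + co^2)
    }
    e_fwd[i] <- energy(ch$fwd)
    e_bwd[i] <- energy(ch$bwd)
    net[i] <- e_fwd[i] - e_bwd[i]
  }
  tot <- max(e_fwd + e_bwd, 1e-300)
  no_decision <- max(abs(net)) <= no_decision_tol * max(tot)
  idx <- which.max(abs(net))
  list(speeds = speeds, net = net, energy_fwd = e_fwd, energy_bwd = e_bwd,
       chosen_speed = if (no_decision) NA_real_ else speeds[idx],
       chosen_direction = if (no_decision) NA_real_ else sign(net[idx]),
       no_decision = no_decision)
}

#' Decoding error rates and accuracy cost
#'
#' Error rate = 1 - (#correct / #trials); a no-decision counts as
#' incorrect. Accuracy cost = success rate x (total spikes / number of
#' cells), the spike expenditure per unit of successful speed transmission.
#'
#' @param decisions data.frame with columns `kind, sf0, speed, trial,
#'   chosen_speed` (NA for no-decision) and optionally `chosen_direction`
#'   (a correct trial must have decoded forward motion).
#' @param spikes the `spike_data` the decisions were computed from (spike
#'   counts enter the accuracy cost).
#' @param n_cells population size.
#' @return list: `per_condition` (error rate per kind/sf0/speed),
#'   `per_kind` (`error_rate`, `success_rate`, `total_spikes`,
#'   `accuracy_cost`).
#' @export
decoding_metrics <- function(decisions, spikes, n_cells) {
  stopifnot(nrow(decisions) > 0, n_cells >= 1)
  decisions$correct <- !is.na(decisions$chosen_speed) &
    abs(decisions$chosen_speed - decisions$speed) < 1e-9
  if ("chosen_direction" %in% names(decisions)) {
    decisions$correct <- decisions$correct &
      !is.na(decisions$chosen_direction) & decisions$chosen_direction > 0
  }
  per_cond <- stats::aggregate(correct ~ kind + sf0 + speed, decisions, mean)
  per_cond$error_rate <- 1 - per_cond$correct
  per_cond$correct <- NULL
  kinds <- unique(decisions$kind)
  per_kind <- do.call(rbind, lapply(kinds, function(k) {
    dk <- decisions[decisions$kind == k, ]
    succ <- mean(dk$correct)
    nspk <- sum(spikes$kind == k)
    data.frame(kind = k, error_rate = 1 - succ, success_rate = succ,
               total_spikes = nspk,
               accuracy_cost = succ * nspk / n_cells,
               stringsAsFactors = FALSE)
  }))
  list(per_condition = per_cond, per_kind = per_kind)
}

#' Space-time image of a movie
#'
#' Collapses a movie over the axis orthogonal to motion (mean over rows),
#' giving the space x time intensity image the decoder consumes.
#'
#' @param movie a `stimulus_movie`.
#' @return matrix (space x time).
#' @export
as_xt <- function(movie) {
  stopifnot(inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  out <- vapply(seq_len(d[1]), function(t) colMeans(movie$frames[t, , ]),
                numeric(d[3]))
  out
}
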