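#' Stimulus condition grid used throughout the protocol
#'
#' The protocol crosses six spatial frequencies with five speeds and three
#' stimulus classes (drifting grating, narrow-bandwidth motion cloud,
#' broad-bandwidth motion cloud). The grating temporal frequency is
#' `sf0 * speed` so that all classes share the same nominal speeds. The
#' narrow-bandwidth values are a fixed preset chosen so that adjacent
#' spectral envelopes do not overlap; the broad preset sets the bandwidth
#' equal to the central spatial frequency so adjacent envelopes touch along
#' the constant-speed plane.
#'
#' @param kinds character subset of `c("grating", "mc_narrow", "mc_broad")`.
#' @param sf0 spatial frequencies, cycles/mm.
#' @param speeds speeds, mm/s.
#' @return data.frame with columns `kind`, `sf0`, `speed`, `tf` (Hz, gratings
#'   only, `NA` otherwise) and `b_sf` (cycles/mm; 0 for gratings).
#' @export
#' @examples
#' head(condition_grid())
condition_grid <- function(kinds = c("grating", "mc_narrow", "mc_broad"),
                           sf0 = c(0.66, 0.9, 1.26, 1.8, 2.52, 3.6),
                           speeds = c(0.25, 0.5, 1.0, 2.0, 4.0)) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  grid <- expand.grid(speed = speeds, sf0 = sf0, kind = kinds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("kind", "sf0", "speed")]
  grid$tf <- ifelse(grid$kind == "grating", grid$sf0 * grid$speed, NA_real_)
  grid$b_sf <- ifelse(grid$kind == "grating", 0,
                      ifelse(grid$kind == "mc_broad", grid$sf0,
                             narrow_bandwidth(grid$sf0)))
  rownames(grid) <- NULL
  grid
}

#' Narrow-bandwidth preset for a central spatial frequency
#'
#' Fixed table mapping the six protocol spatial frequencies to the
#' narrow-bandwidth spectral widths (chosen so that adjacent envelopes do
#' not overlap). Values outside the table are interpolated linearly.
#'
#' @param sf0 central spatial frequency, cycles/mm.
#' @return bandwidth, cycles/mm.
#' @export
narrow_bandwidth <- function(sf0) {
  sf_tab <- c(0.66, 0.9, 1.26, 1.8, 2.52, 3.6)
  b_tab <- c(0.24, 0.36, 0.54, 0.72, 1.08, 1.5)
  stats::approx(sf_tab, b_tab, xout = sf0, rule = 2)$y
}

new_stimulus_movie <- function(frames, frame_rate, px_per_mm, kind,
                               sf0 = NA_real_, speed = NA_real_,
                               b_sf = NA_real_, duration, seed = NULL,
                               meta = list()) {
  structure(list(frames = frames, frame_rate = frame_rate,
                 px_per_mm = px_per_mm, kind = kind, sf0 = sf0,
                 speed = speed, b_sf = b_sf, duration = duration,
                 seed = seed, meta = meta),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_movie> %s: %d frames of %d x %d px @ %g Hz (%g s)\n",
              x$kind, d[1], d[2], d[3], x$frame_rate, x$duration))
  cat(sprintf("  sf0 = %g cycles/mm, speed = %g mm/s, b_sf = %g cycles/mm, %g px/mm\n",
              x$sf0, x$speed, x$b_sf, x$px_per_mm))
  invisible(x)
}

#' Drifting sinusoidal grating
#'
#' Full-contrast sinusoid translating along the horizontal axis; positive
#' speed moves the pattern toward increasing x. The dominant temporal
#' frequency is `sf0 * speed`. Luminance is normalized to `[0, 1]`
#' (Michelson contrast 1).
#'
#' @param sf0 spatial frequency, cycles/mm (> 0).
#' @param speed drift speed, mm/s (>= 0; 0 gives a static pattern).
#' @param duration seconds.
#' @param frame_rate Hz.
#' @param size_px image side, pixels (movies are square).
#' @param px_per_mm pixel pitch calibration, pixels per millimetre.
#' @param phase initial phase, radians.
#' @return a `stimulus_movie` with frames indexed `[time, y, x]`.
#' @export
#' @examples
#' mov <- make_drifting_grating(1.8, 1.0, duration = 1, size_px = 32)
#' range(mov$frames)
make_drifting_grating <- function(sf0, speed, duration = 3, frame_rate = 60,
                                  size_px = 128, px_per_mm = 240, phase = 0) {
  stopifnot_positive(sf0 = sf0, duration = duration, frame_rate = frame_rate,
                     size_px = size_px, px_per_mm = px_per_mm)
  stopifnot_positive(speed = speed, .allow_zero = TRUE)
  nt <- round(duration * frame_rate)
  sf_px <- sf0 / px_per_mm                 # cycles per pixel
  tf <- sf0 * speed                        # Hz
  x <- seq_len(size_px) - 1
  frames <- array(0, dim = c(nt, size_px, size_px))
  for (t in seq_len(nt)) {
    row <- sin(2 * pi * (sf_px * x - tf * (t - 1) / frame_rate) + phase)
    frames[t, , ] <- matrix(row, nrow = size_px, ncol = size_px, byrow = TRUE)
  }
  frames <- normalize_01(frames)
  new_stimulus_movie(frames, frame_rate, px_per_mm, "grating", sf0, speed,
                     0, duration, meta = list(tf = tf, phase = phase))
}

#' Band-limited random-phase motion texture (motion cloud)
#'
#' Synthesizes a dynamic texture whose power-spectral envelope is the
#' product of (i) a log-Gaussian radial spatial-frequency envelope centred
#' at `sf0` with width mapped from `b_sf` and a `1/f` colour factor,
#' (ii) a Gaussian envelope around the plane of constant speed
#' (`f_t = -speed * f_x`), and (iii) a Gaussian orientation envelope about
#' the horizontal motion axis. Phases are i.i.d. uniform, so identical
#' parameters and seed give bit-identical movies.
#'
#' @inheritParams make_drifting_grating
#' @param b_sf spatial-frequency bandwidth, cycles/mm (>= 0; 0 is treated
#'   as `sf0/100`, the quasi-grating limit).
#' @param b_v speed-plane bandwidth as a fraction of the central temporal
#'   frequency (default 0.1, i.e. ~±10%).
#' @param b_theta orientation bandwidth about the motion axis, radians.
#' @param seed integer; fixes the random phases.
#' @return a `stimulus_movie`; `meta$alias_truncated` records whether the
#'   envelope had to be truncated at the spatial Nyquist frequency.
#' @export
make_motion_cloud <- function(sf0, speed, b_sf, b_v = 0.1,
                              b_theta = 15 * pi / 180, duration = 3,
                              frame_rate = 60, size_px = 128, px_per_mm = 240,
                              seed = NULL) {
  stopifnot_positive(sf0 = sf0, duration = duration, frame_rate = frame_rate,
                     size_px = size_px, px_per_mm = px_per_mm)
  stopifnot_positive(b_sf = b_sf, speed = speed, .allow_zero = TRUE)
  nt <- round(duration * frame_rate)
  nx <- size_px

  ft <- fft_freqs(nt) * frame_rate         # Hz
  fx <- fft_freqs(nx) * px_per_mm          # cycles/mm, along motion axis
  fy <- fft_freqs(nx) * px_per_mm

  nyquist <- px_per_mm / 2
  alias_truncated <- (sf0 + 2 * b_sf) > nyquist
  if (alias_truncated) {
    warning("spectral envelope extends past the spatial Nyquist frequency; ",
            "envelope truncated", call. = FALSE)
  }

  b_sf_eff <- if (b_sf <= 0) sf0 / 100 else b_sf
  s_log <- log1p(b_sf_eff / sf0)           # log-Gaussian width
  sigma_t <- max(b_v * sf0 * abs(speed), 1 / duration)

  fr2 <- outer(fy^2, fx^2, "+")            # [y, x] squared radial frequency
  fr <- sqrt(fr2)
  rad <- matrix(0, nx, nx)
  pos <- fr > 0
  rad[pos] <- (1 / fr[pos]) * exp(-(log(fr[pos] / sf0))^2 / (2 * s_log^2))
  th <- atan2(abs(outer(fy, rep(1, nx))), abs(outer(rep(1, nx), fx)))
  orient <- exp(-th^2 / (2 * b_theta^2))
  spatial_env <- rad * orient              # [y, x]

  fx_mat <- matrix(fx, nx, nx, byrow = TRUE)    # [y, x]
  env <- array(0, dim = c(nt, nx, nx))
  for (t in seq_len(nt)) {
    env[t, , ] <- spatial_env * exp(-(ft[t] + speed * fx_mat)^2 / (2 * sigma_t^2))
  }

  phases <- with_seed(seed, array(stats::runif(nt * nx * nx, 0, 2 * pi),
                                  dim = c(nt, nx, nx)))
  spectrum <- env * exp(1i * phases)
  frames <- Re(stats::fft(spectrum, inverse = TRUE)) / length(spectrum)
  frames <- normalize_01(frames)
  kind <- if (b_sf >= sf0) "mc_broad" else "mc_narrow"
  new_stimulus_movie(frames, frame_rate, px_per_mm, kind, sf0, speed, b_sf,
                     duration, seed,
                     meta = list(b_v = b_v, b_theta = b_theta,
                                 alias_truncated = alias_truncated))
}

#' White-noise checkerboard
#'
#' Binary checkerboard for receptive-field mapping: each block independently
#' takes luminance 0 or 1 per frame with probability 1/2. Frames are stored
#' at one pixel per block (exact for a blockwise-constant stimulus), so the
#' stored calibration is `px_per_mm = 1 / block_size_mm`.
#'
#' @param block_size_mm block side, mm.
#' @param n_blocks blocks per side.
#' @param duration seconds.
#' @param frame_rate Hz.
#' @param seed integer RNG seed.
#' @return a `stimulus_movie` of kind `"checkerboard"`.
#' @export
make_checkerboard <- function(block_size_mm = 0.05, n_blocks = 35,
                              duration = 1200, frame_rate = 60, seed = NULL) {
  stopifnot_positive(block_size_mm = block_size_mm, n_blocks = n_blocks,
                     duration = duration, frame_rate = frame_rate)
  nt <- round(duration * frame_rate)
  frames <- with_seed(seed, array(stats::rbinom(nt * n_blocks * n_blocks, 1, 0.5),
                                  dim = c(nt, n_blocks, n_blocks)))
  new_stimulus_movie(frames, frame_rate, 1 / block_size_mm, "checkerboard",
                     duration = duration, seed = seed,
                     meta = list(block_size_mm = block_size_mm,
                                 n_blocks = n_blocks))
}

#' Contrast diagnostics of a stimulus movie
#'
#' Michelson contrast `(max - min) / (max + min)` of the whole movie and the
#' distribution of per-pixel Weber contrasts `(I - mean(I)) / mean(I)`.
#'
#' @param movie a `stimulus_movie`.
#' @param n_bins histogram bins for the Weber distribution.
#' @return list with `michelson`, `weber_histogram` (data.frame `mid`,
#'   `mass` summing to 1), `weber_min`, `weber_max`, `weber_kurtosis`
#'   (excess kurtosis of the Weber values).
#' @export
contrast_profile <- function(movie, n_bins = 50) {
  stopifnot(inherits(movie, "stimulus_movie"))
  v <- as.numeric(movie$frames)
  if (length(v) == 0) stop("empty movie", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("Weber contrast undefined: movie mean luminance is 0",
                   call. = FALSE)
  rng <- range(v)
  michelson <- if (sum(rng) == 0) 0 else diff(rng) / sum(rng)
  weber <- (v - m) / m
  h <- graphics::hist(weber, breaks = n_bins, plot = FALSE)
  mass <- h$counts / sum(h$counts)
  k <- mean((weber - mean(weber))^4) / stats::var(weber)^2 - 3
  list(michelson = michelson,
       weber_histogram = data.frame(mid = h$mids, mass = mass),
       weber_min = min(weber), weber_max = max(weber),
       weber_kurtosis = k)
}

#' Measure the temporal frequency of a drifting grating movie
#'
#' Demodulates each frame against the movie's carrier spatial frequency by
#' exact least squares (regressing one image row onto the sine and cosine
#' of the carrier), tracks the recovered phase across frames, and returns
#' the magnitude of its phase slope in Hz. For a rigidly translating
#' sinusoid this is exact to machine precision even when the spatial or
#' temporal frequency falls between DFT grid points, unlike FFT peak
#' binning.
#'
#' @param movie a `stimulus_movie` of kind `"grating"`.
#' @param row image row to analyse (default: middle row).
#' @return temporal frequency, Hz.
#' @export
measure_temporal_frequency <- function(movie, row = NULL) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (!identical(movie$kind, "grating")) {
    stop("phase demodulation requires a single-carrier (grating) movie",
         call. = FALSE)
  }
  d <- dim(movie$frames)
  row <- row %||% max(1L, d[2] %/% 2)
  x <- seq_len(d[3]) - 1
  a <- 2 * pi * movie$sf0 / movie$px_per_mm      # rad per pixel
  design <- cbind(1, sin(a * x), cos(a * x))
  coefs <- qr.solve(design, t(movie$frames[, row, ]))  # 3 x time
  ph <- atan2(coefs[3, ], coefs[2, ])            # phase of sin(ax + ph)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi             # unwrap steps
  abs(mean(dph)) / (2 * pi) * movie$frame_rate
}

#' Convert spatial frequency between physical and pixel units
#'
#' @param sf spatial frequency.
#' @param px_per_mm calibration, pixels per millimetre.
#' @param to `"px"` (cycles/mm -> cycles/px) or `"mm"` (the inverse).
#' @return converted spatial frequency.
#' @export
convert_sf <- function(sf, px_per_mm, to = c("px", "mm")) {
  to <- match.arg(to)
  stopifnot_positive(px_per_mm = px_per_mm)
  if (to == "px") sf / px_per_mm else sf * px_per_mm
}
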