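# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds derived from one master seed, kept below 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(stimuli = 101L, population = 211L, responses = 307L,
               tuning = 401L, sta = 503L, decode = 601L, screen = 701L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1103L + off) %% 2147483629)
}

stopifnot_positive <- function(..., .allow_zero = FALSE) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    bad <- if (.allow_zero) any(!is.finite(v)) || any(v < 0) else
      any(!is.finite(v)) || any(v <= 0)
    if (bad) {
      stop(sprintf("invalid parameter: `%s` must be %s",
                   nms[i], if (.allow_zero) "finite and >= 0" else "finite and > 0"),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# DFT sample frequencies in cycles per sample, fftfreq convention.
fft_freqs <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

# Rescale to [0, 1] with Michelson contrast 1; constant input maps to 0.5.
normalize_01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(array(0.5, dim = dim(x) %||% length(x)))
  (x - rng[1]) / diff(rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Short content checksum used to stamp run reports (not cryptographic).
config_checksum <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
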