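# Internal numerics shared by the DSP and synthesis layers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Symmetric Blackman window of length n (n >= 1).
blackman_window <- function(n) {
  if (n == 1L) return(1)
  k <- seq_len(n) - 1L
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(pi * x[nz]) / (pi * x[nz])
  out
}

# Blackman-windowed sinc low-pass prototype. `fc` is the cutoff in
# cycles/sample (0 < fc < 0.5); `taps` is forced odd so the group delay is an
# integer number of samples. DC gain normalized to exactly 1.
design_lowpass_fir <- function(fc, taps) {
  taps <- as.integer(taps)
  if (taps %% 2L == 0L) taps <- taps + 1L
  half <- (taps - 1L) %/% 2L
  m <- seq(-half, half)
  h <- 2 * fc * sinc(2 * fc * m) * blackman_window(taps)
  h / sum(h)
}

# Full ("open") linear convolution via FFT; returns length(x)+length(h)-1.
convolve_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nf
  y[seq_len(n)]
}

# Smallest p/q (q <= max_den) with p/q == target_fs/fs to within 1e-9
# relative error. Errors with class pwv_unsupported_ratio when none exists.
rate_ratio <- function(fs, target_fs, max_den = 10000L) {
  r <- target_fs / fs
  q <- seq_len(max_den)
  p <- round(r * q)
  ok <- p >= 1 & p <= max_den & abs(p / q - r) <= 1e-9 * r
  if (!any(ok)) {
    pwv_abort(
      "unsupported_ratio",
      sprintf("target_fs/fs = %.9g is not expressible as p/q with p,q <= %d", r, max_den)
    )
  }
  i <- which(ok)[1L]
  list(p = as.integer(p[i]), q = as.integer(q[i]))
}
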