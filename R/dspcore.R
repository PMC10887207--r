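#' Nyquist criterion check
#'
#' A sampled signal with band limit B can be reconstructed flawlessly iff
#' `B < fs/2` (strict). Returns that predicate.
#'
#' @param fs Sampling rate, Hz (> 0).
#' @param band_limit Highest frequency component B, Hz (> 0).
#' @return Logical scalar.
#' @examples
#' nyquist_ok(250, 120) # TRUE
#' nyquist_ok(125, 120) # FALSE: 120 >= 62.5
#' @export
nyquist_ok <- function(fs, band_limit) {
  check_positive_scalar(fs, "fs")
  check_positive_scalar(band_limit, "band_limit")
  band_limit < fs / 2
}

#' Apparent (folded) frequency under sampling
#'
#' Frequency content above `fs/2` folds to the apparent frequency
#' `|f - fs * round(f/fs)|`, always in `[0, fs/2]`.
#'
#' @param f True frequency, Hz (>= 0).
#' @param fs Sampling rate, Hz (> 0).
#' @return Apparent frequency in Hz.
#' @examples
#' alias_frequency(60, 250)  # 60: below Nyquist, unchanged
#' alias_frequency(120, 125) # 5: the fold that corrupts the pulse band
#' @export
alias_frequency <- function(f, fs) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    pwv_abort("invalid_argument", "`f` must be non-negative and finite")
  }
  check_positive_scalar(fs, "fs")
  abs(f - fs * round(f / fs))
}

#' Bandlimited (Nyquist-Shannon) resampling
#'
#' Rational polyphase resampling: the finite-length realization of sinc
#' reconstruction. The rate ratio must reduce to p/q with p, q <= 10^4. The
#' signal is upsampled by p (zero stuffing), filtered by a Blackman-windowed
#' sinc anti-imaging/anti-aliasing FIR with cutoff `min(fs, target_fs)/2`
#' (stopband > 70 dB), and decimated by q. The FIR is linear-phase with its
#' integer group delay removed exactly, so waveform features keep their
#' absolute times, and the signal mean is carried around the filter so DC is
#' preserved exactly.
#'
#' @param ts A non-empty [time_series()].
#' @param target_fs Output sampling rate, Hz (> 0).
#' @return A `pwv_ts` at `target_fs` with `ceiling(n * p / q)` samples and the
#'   same `start_time`.
#' @examples
#' ts <- time_series(sin(2 * pi * 2 * (0:2499) / 250), fs = 250)
#' hi <- resample_bandlimited(ts, 10000)
#' length(hi$samples) # 2500 * 40
#' @export
resample_bandlimited <- function(ts, target_fs) {
  stopifnot(inherits(ts, "pwv_ts"))
  check_positive_scalar(target_fs, "target_fs")
  n <- length(ts$samples)
  if (n == 0L) pwv_abort("invalid_argument", "cannot resample an empty series")
  pq <- rate_ratio(ts$fs, target_fs)
  p <- pq$p
  q <- pq$q
  n_out <- ceiling(n * p / q)
  if (p == 1L && q == 1L) {
    return(time_series(ts$samples, fs = target_fs, start_time = ts$start_time,
                       band_limit_hint = ts$band_limit_hint))
  }
  mu <- mean(ts$samples)
  up <- numeric(n * p)
  up[seq(1L, by = p, length.out = n)] <- (ts$samples - mu) * p
  max_pq <- max(p, q)
  half <- 10L * max_pq
  h <- design_lowpass_fir(fc = 0.5 / max_pq, taps = 2L * half + 1L)
  y <- convolve_full(up, h)
  y <- y[(half + 1L):(half + n * p)] # exact integer group-delay compensation
  out <- y[seq(1L, by = q, length.out = n_out)] + mu
  hint <- min(ts$fs, target_fs) / 2
  if (!is.null(ts$band_limit_hint)) hint <- min(hint, ts$band_limit_hint)
  time_series(out, fs = target_fs, start_time = ts$start_time, band_limit_hint = hint)
}

#' Zero-phase 10 Hz low-pass filter
#'
#' Blackman-windowed sinc FIR low-pass (odd length, ~5 Hz transition width,
#' stopband > 70 dB, DC gain exactly 1) applied with its integer group delay
#' compensated, so output timestamps align with the input and pulse peaks are
#' not shifted. The 10 Hz default removes mains interference and measurement
#' noise while passing the pulse band (heart-rate fundamental 1-5 Hz plus
#' harmonics).
#'
#' @param ts A [time_series()].
#' @param cutoff Cutoff frequency, Hz; must satisfy `cutoff < fs/2`.
#' @param transition Transition width, Hz (sets the filter length).
#' @return Filtered `pwv_ts`, same length, fs and start time.
#' @export
lowpass10 <- function(ts, cutoff = 10, transition = 5) {
  stopifnot(inherits(ts, "pwv_ts"))
  check_positive_scalar(cutoff, "cutoff")
  check_positive_scalar(transition, "transition")
  if (cutoff >= ts$fs / 2) {
    pwv_abort("invalid_argument", sprintf("cutoff %g Hz must be below Nyquist (%g Hz)", cutoff, ts$fs / 2))
  }
  n <- length(ts$samples)
  if (n == 0L) pwv_abort("invalid_argument", "cannot filter an empty series")
  # Blackman transition width ~ 5.5/taps cycles/sample.
  taps <- ceiling(5.5 * ts$fs / transition)
  if (taps %% 2L == 0L) taps <- taps + 1L
  half <- (taps - 1L) %/% 2L
  h <- design_lowpass_fir(fc = cutoff / ts$fs, taps = taps)
  mu <- mean(ts$samples)
  y <- convolve_full(ts$samples - mu, h)
  y <- y[(half + 1L):(half + n)] + mu
  time_series(y, fs = ts$fs, start_time = ts$start_time,
              band_limit_hint = min(cutoff, ts$band_limit_hint %||% cutoff))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First-derivative channel
#'
#' Central first difference scaled by `fs` (one-sided at the endpoints);
#' used as a visualization/QA channel that accentuates pulse upstrokes.
#'
#' @param ts A [time_series()] with at least two samples.
#' @return `pwv_ts` of the same length and rate.
#' @export
derivative <- function(ts) {
  stopifnot(inherits(ts, "pwv_ts"))
  x <- ts$samples
  n <- length(x)
  if (n < 2L) pwv_abort("invalid_argument", "derivative needs at least 2 samples")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * ts$fs
  d[n] <- (x[n] - x[n - 1]) * ts$fs
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * ts$fs / 2
  time_series(d, fs = ts$fs, start_time = ts$start_time, band_limit_hint = ts$band_limit_hint)
}

#' Blackman-windowed segment spectra
#'
#' Cuts the signal into non-overlapping full segments of `seg_duration`
#' seconds (a trailing partial segment is discarded), removes each segment's
#' mean, applies a Blackman window (low sidelobes, little spectral leakage),
#' and computes the one-sided magnitude spectrum. The dominant frequency of a
#' segment is the magnitude argmax at frequencies `>= floor_freq`; the floor
#' excludes DC and baseline wander.
#'
#' @param ts A [time_series()].
#' @param seg_duration Segment length in seconds (default 5).
#' @param floor_freq Lower bound of the dominant-frequency search, Hz.
#' @return List of segments; each has `index`, `start_time`, `frequencies`,
#'   `magnitudes`, `dominant_freq`.
#' @export
spectral_segments <- function(ts, seg_duration = 5, floor_freq = 0.5) {
  stopifnot(inherits(ts, "pwv_ts"))
  check_positive_scalar(seg_duration, "seg_duration")
  check_nonneg_scalar(floor_freq, "floor_freq")
  nseg <- floor(seg_duration * ts$fs)
  if (nseg < 16) pwv_abort("invalid_argument", "segment must contain at least 16 samples")
  n_full <- floor(length(ts$samples) / nseg)
  if (n_full < 1) pwv_abort("invalid_argument", "signal shorter than one segment")
  w <- blackman_window(nseg)
  freqs <- (0:(nseg %/% 2)) * ts$fs / nseg
  lapply(seq_len(n_full), function(i) {
    seg <- ts$samples[((i - 1L) * nseg + 1L):(i * nseg)]
    spec <- Mod(stats::fft((seg - mean(seg)) * w))[seq_along(freqs)]
    searchable <- which(freqs >= floor_freq)
    dom <- freqs[searchable[which.max(spec[searchable])]]
    list(index = i,
         start_time = ts$start_time + (i - 1L) * nseg / ts$fs,
         frequencies = freqs,
         magnitudes = spec,
         dominant_freq = dom)
  })
}

#' Zero-normalized cross-correlation at zero lag
#'
#' Subtracts each signal's mean and divides the inner product by the product
#' of the centered Euclidean norms. 1 means identical shape; the measure is
#' invariant to positive affine amplitude transforms of either input. Zero
#' lag is deliberate: the package's filters are zero-phase, so a time shift
#' between reference and reconstruction is an error that ZNCC should expose,
#' not hide.
#'
#' @param a,b [time_series()] objects with equal `fs` and equal length.
#' @return A number in `[-1, 1]`.
#' @examples
#' x <- time_series(sin(1:100), fs = 10)
#' y <- time_series(2 * sin(1:100) + 3, fs = 10)
#' zncc(x, y) # 1: affine invariance
#' @export
zncc <- function(a, b) {
  stopifnot(inherits(a, "pwv_ts"), inherits(b, "pwv_ts"))
  if (abs(a$fs - b$fs) > 1e-9 * a$fs) {
    pwv_abort("invalid_argument", "inputs must share a sampling rate")
  }
  if (length(a$samples) != length(b$samples)) {
    pwv_abort("invalid_argument", "inputs must have equal length")
  }
  ac <- a$samples - mean(a$samples)
  bc <- b$samples - mean(b$samples)
  na <- sqrt(sum(ac^2))
  nb <- sqrt(sum(bc^2))
  if (na == 0 || nb == 0) {
    pwv_abort("undefined_correlation", "ZNCC undefined for a zero-variance input")
  }
  sum(ac * bc) / (na * nb)
}

#' Reconstruction fidelity (ZNCC after alignment)
#'
#' Quantifies how well a low-rate acquisition reproduces a high-rate
#' reference: the low-rate series is bandlimited-resampled to the reference
#' rate, both are low-pass filtered at 10 Hz, `edge_trim` seconds are dropped
#' from each end (filter transients), and the zero-lag [zncc()] is returned.
#'
#' @param reference High-rate reference `pwv_ts`.
#' @param low_rate Low-rate acquisition `pwv_ts` (`low_rate$fs <= reference$fs`).
#' @param edge_trim Seconds trimmed from each end before comparison.
#' @return ZNCC in `[-1, 1]`.
#' @export
reconstruction_fidelity <- function(reference, low_rate, edge_trim = 0.5) {
  stopifnot(inherits(reference, "pwv_ts"), inherits(low_rate, "pwv_ts"))
  if (reference$fs < low_rate$fs) {
    pwv_abort("invalid_argument", "`reference` must have the higher (or equal) sampling rate")
  }
  check_nonneg_scalar(edge_trim, "edge_trim")
  recon <- resample_bandlimited(low_rate, reference$fs)
  ref_f <- lowpass10(reference)
  rec_f <- lowpass10(recon)
  k <- round(edge_trim * reference$fs)
  n <- min(length(ref_f$samples), length(rec_f$samples))
  if (n - 2 * k < reference$fs) {
    pwv_abort("insufficient_overlap", "less than 1 s of signal remains after edge trimming")
  }
  idx <- (k + 1L):(n - k)
  zncc(time_series(ref_f$samples[idx], reference$fs),
       time_series(rec_f$samples[idx], reference$fs))
}
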