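#' Uniformly sampled time series
#'
#' Container for one uniformly sampled channel: amplitudes, sampling rate,
#' absolute start time, and an optional band-limit hint (the highest frequency
#' believed present, in Hz), used by Nyquist diagnostics.
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param fs Sampling rate in Hz (> 0). The sample period is `1/fs`.
#' @param start_time Time of the first sample in seconds.
#' @param band_limit_hint Highest frequency component in Hz, or `NULL`.
#'
#' @return An object of class `"pwv_ts"`.
#' @examples
#' ts <- time_series(sin(2 * pi * 2 * (0:999) / 250), fs = 250)
#' ts_duration(ts)
#' @export
time_series <- function(samples, fs, start_time = 0, band_limit_hint = NULL) {
  check_positive_scalar(fs, "fs")
  if (!is.numeric(samples)) {
    pwv_abort("invalid_argument", "`samples` must be numeric")
  }
  if (length(samples) && any(!is.finite(samples))) {
    pwv_abort("invalid_argument", "`samples` must be finite")
  }
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time)) {
    pwv_abort("invalid_argument", "`start_time` must be a single finite number")
  }
  if (!is.null(band_limit_hint)) check_positive_scalar(band_limit_hint, "band_limit_hint")
  structure(
    list(
      samples = as.numeric(samples),
      fs = as.numeric(fs),
      start_time = as.numeric(start_time),
      band_limit_hint = band_limit_hint
    ),
    class = "pwv_ts"
  )
}

#' @rdname time_series
#' @param ts A `pwv_ts` object.
#' @export
ts_times <- function(ts) {
  ts$start_time + (seq_along(ts$samples) - 1) / ts$fs
}

#' @rdname time_series
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$fs

#' @export
print.pwv_ts <- function(x, ...) {
  cat(sprintf(
    "<pwv_ts> %d samples @ %g Hz (%.3f s), start %.6g s%s\n",
    length(x$samples), x$fs, ts_duration(x), x$start_time,
    if (is.null(x$band_limit_hint)) "" else sprintf(", band limit ~%g Hz", x$band_limit_hint)
  ))
  invisible(x)
}

#' Two-channel pulse recording
#'
#' A synchronized proximal/distal pair of [time_series()] channels together
#' with the inter-electrode distance along the artery. The default distance,
#' 3.2 cm, is the spacing of closely placed wrist electrodes over the radial
#' artery.
#'
#' @param prox,dist Proximal and distal channels (`pwv_ts`), equal `fs`,
#'   equal length, equal `start_time`.
#' @param distance Electrode separation in meters (> 0).
#' @param provenance Free-form metadata list (e.g. the generating
#'   [synth_config()] and ground-truth beat onsets).
#'
#' @return An object of class `"pwv_recording"`.
#' @export
pulse_recording <- function(prox, dist, distance = 0.032, provenance = list()) {
  if (!inherits(prox, "pwv_ts") || !inherits(dist, "pwv_ts")) {
    pwv_abort("invalid_argument", "`prox` and `dist` must be pwv_ts objects")
  }
  if (abs(prox$fs - dist$fs) > 1e-9 * prox$fs) {
    pwv_abort("invalid_argument", "channels must share the same sampling rate")
  }
  if (length(prox$samples) != length(dist$samples)) {
    pwv_abort("invalid_argument", "channels must have equal length")
  }
  check_positive_scalar(distance, "distance")
  structure(
    list(prox = prox, dist = dist, distance = as.numeric(distance), provenance = provenance),
    class = "pwv_recording"
  )
}

#' @export
print.pwv_recording <- function(x, ...) {
  cat(sprintf(
    "<pwv_recording> 2 channels x %d samples @ %g Hz (%.3f s), distance %.4g m\n",
    length(x$prox$samples), x$prox$fs, ts_duration(x$prox), x$distance
  ))
  invisible(x)
}
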