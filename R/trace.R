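#' Construct a pressure trace
#'
#' A `pressure_trace` holds one channel's uniformly sampled pressure series:
#' the channel label, the sampling rate, the session time of the first
#' sample, and the pressure values in mmHg.
#'
#' @param values Numeric vector of pressures in mmHg (finite, length >= 2).
#' @param fs Sampling rate in Hz (positive).
#' @param channel Channel label, one of `"RK"`, `"RB"`, `"LK"`, `"LB"`.
#' @param t0 Session time (seconds) of the first sample. Default 0.
#' @return An object of class `pressure_trace`.
#' @examples
#' tr <- pressure_trace(50 + sin(seq(0, 10, by = 1 / 28)), fs = 28, channel = "RK")
#' tr
#' @export
pressure_trace <- function(values, fs, channel, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a pressure trace needs at least two samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("pressure trace values must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("sampling rate 'fs' must be a single positive number", call. = FALSE)
  }
  channel <- match.arg(channel, CHANNELS)
  structure(
    list(values = values, fs = fs, channel = channel, t0 = as.numeric(t0)),
    class = "pressure_trace"
  )
}

#' Sample times of a pressure trace
#'
#' @param trace A [pressure_trace()].
#' @return Numeric vector of session times (seconds), one per sample.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' @export
print.pressure_trace <- function(x, ...) {
  dur <- (length(x$values) - 1) / x$fs
  cat(sprintf(
    "<pressure_trace> channel %s: %d samples @ %.6g Hz, t = [%.3f, %.3f] s, range [%.2f, %.2f] mmHg\n",
    x$channel, length(x$values), x$fs, x$t0, x$t0 + dur,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
as.data.frame.pressure_trace <- function(x, ...) {
  data.frame(
    channel = x$channel,
    time_s = trace_times(x),
    pressure_mmHg = x$values,
    stringsAsFactors = FALSE
  )
}

#' @export
length.pressure_trace <- function(x) length(x$values)
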