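#' Construct a dynamometer torque trace
#'
#' A torque trace is one dynamometer trial: sampled time, knee-flexion angle
#' and knee-extensor torque. The angle convention throughout the package is
#' knee-flexion degrees with 0 deg = full extension, so an isokinetic knee
#' extension runs from large to small angles.
#'
#' @param time_s sample times in seconds, strictly increasing.
#' @param angle_deg knee-flexion angle in degrees at each sample.
#' @param torque_Nm knee-extensor torque in N*m at each sample
#'   (extension positive).
#' @param mode trial mode: `"isometric"`, `"isokinetic"` or `"passive"`.
#' @param nominal the nominal condition: target angle (deg) for isometric
#'   trials or target angular speed (deg/s) for isokinetic trials; `NA` for
#'   passive movements.
#'
#' @return A `data.frame` of class `"torque_trace"` with columns `time_s`,
#'   `angle_deg`, `torque_Nm` and attributes `mode` and `nominal`.
#' @export
#' @examples
#' tr <- torque_trace(seq(0, 1, 0.01), rep(60, 101), rep(50, 101),
#'                    mode = "isometric", nominal = 60)
torque_trace <- function(time_s, angle_deg, torque_Nm,
                         mode = c("isometric", "isokinetic", "passive"),
                         nominal = NA_real_) {
  mode <- match.arg(mode)
  n <- length(time_s)
  if (length(angle_deg) != n || length(torque_Nm) != n)
    af_stop("time, angle and torque must have equal length",
            "archforce_input_error")
  if (n < 2L)
    af_stop("a torque trace needs at least two samples",
            "archforce_input_error")
  if (any(!is.finite(time_s)) || any(!is.finite(angle_deg)) ||
      any(!is.finite(torque_Nm)))
    af_stop("torque trace contains non-finite values", "archforce_data_error")
  if (any(diff(time_s) <= 0))
    af_stop("time must be strictly increasing", "archforce_data_error")
  out <- data.frame(time_s = as.numeric(time_s),
                    angle_deg = as.numeric(angle_deg),
                    torque_Nm = as.numeric(torque_Nm))
  attr(out, "mode") <- mode
  attr(out, "nominal") <- nominal
  class(out) <- c("torque_trace", "data.frame")
  out
}

trace_mode <- function(trace) attr(trace, "mode") %||% "isometric"
trace_nominal <- function(trace) attr(trace, "nominal") %||% NA_real_

`%||%` <- function(a, b) if (is.null(a)) b else a

# sampling rate from the median time step (robust to rounding jitter)
trace_fs <- function(trace) 1 / median(diff(trace$time_s))

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("<torque_trace> %s trial (nominal %s), %d samples, %.3g s, peak %.1f N*m\n",
              trace_mode(x), format(trace_nominal(x)), nrow(x),
              diff(range(x$time_s)), max(x$torque_Nm)))
  invisible(x)
}
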