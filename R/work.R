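# Joint and muscle work over the iso-velocity phase.

# restrict a series to the window's time span, with the endpoint samples
# obtained by linear interpolation at exactly start_time and end_time
clip_to_window <- function(time_s, values, window) {
  t0 <- window$start_time; t1 <- window$end_time
  if (t0 < min(time_s) - 1e-12 || t1 > max(time_s) + 1e-12)
    af_stop("window not covered by the series", "archforce_trial_error")
  inside <- which(time_s > t0 & time_s < t1)
  tt <- c(t0, time_s[inside], t1)
  vv <- lapply(values, function(y)
    c(approx(time_s, y, t0)$y, y[inside], approx(time_s, y, t1)$y))
  c(list(time_s = tt), vv)
}

#' Joint work over the iso-velocity phase
#'
#' Trapezoidal integral of joint torque over joint angle (converted to
#' radians) between the window's start and end angles (80 to 50 deg flexion
#' by default). The integration variable is angle, with the endpoint
#' (angle, torque) pairs obtained by linear interpolation exactly at the
#' window angles, so work is additive across sub-windows. Extension torque
#' during extension gives positive work.
#'
#' @param trace a [torque_trace()] (filtered and passive-corrected).
#' @param window an [isovelocity_window()] for this trace.
#' @return work in J.
#' @export
#' @examples
#' # constant 100 N*m over 80 -> 50 deg: 100 * 30 * pi / 180 = 52.36 J
joint_work <- function(trace, window) {
  w <- clip_to_window(trace$time_s,
                      list(angle = trace$angle_deg, tq = trace$torque_Nm),
                      window)
  # traversal from larger to smaller flexion angle = extension; the sign
  # flip makes extension torque produce positive work
  -trapz(deg2rad(w$angle), w$tq)
}

#' Muscle work over the iso-velocity phase
#'
#' Trapezoidal integral of muscle force over muscle-length change
#' (millimetres converted to metres) within the window; positive for
#' shortening under tension. Force and muscle length must be on the same
#' time base.
#'
#' @param series data frame with columns `time_s`, `force_N`,
#'   `muscle_length_mm`, time-aligned and covering the window.
#' @param window an [isovelocity_window()].
#' @return work in J.
#' @export
muscle_work <- function(series, window) {
  need <- c("time_s", "force_N", "muscle_length_mm")
  if (!all(need %in% names(series)))
    af_stop("series must carry time_s, force_N and muscle_length_mm",
            "archforce_input_error")
  if (any(!is.finite(series$force_N)) ||
      any(!is.finite(series$muscle_length_mm)))
    af_stop("misaligned or incomplete force/length series",
            "archforce_input_error")
  w <- clip_to_window(series$time_s,
                      list(F = series$force_N, Lm = series$muscle_length_mm),
                      window)
  -trapz(w$Lm / 1000, w$F)   # shortening (decreasing Lm) = positive work
}
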