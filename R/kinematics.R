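# Fascicle kinematics: velocities, muscle length, iso-velocity windows,
# windowed peak extraction.

#' Fascicle shortening velocity by central differences
#'
#' Interior samples use the central difference
#' `v(t_i) = -(L(t_{i+1}) - L(t_{i-1})) / (t_{i+1} - t_{i-1})`; the
#' endpoints use one-sided differences. Shortening is positive, so the
#' force-velocity relation has its conventional descending limb.
#'
#' @param series a data frame with columns `time_s` and
#'   `fascicle_length_mm` (at least 3 samples, strictly increasing time).
#' @return numeric vector of shortening velocities, mm/s.
#' @export
#' @examples
#' s <- data.frame(time_s = c(0, .1, .2), fascicle_length_mm = c(100, 99, 98))
#' fascicle_velocity(s)  # 10 mm/s everywhere
fascicle_velocity <- function(series) {
  t <- series$time_s
  L <- series$fascicle_length_mm
  n <- length(t)
  if (n < 3L)
    af_stop("at least 3 samples are needed for central differences",
            "archforce_signal_error")
  if (any(diff(t) <= 0))
    af_stop("duplicate or decreasing timestamps", "archforce_signal_error")
  v <- numeric(n)
  i <- 2:(n - 1)
  v[i] <- -(L[i + 1] - L[i - 1]) / (t[i + 1] - t[i - 1])
  v[1] <- -(L[2] - L[1]) / (t[2] - t[1])
  v[n] <- -(L[n] - L[n - 1]) / (t[n] - t[n - 1])
  v
}

#' Muscle length from fascicle length and pennation
#'
#' The length of the muscle along its line of action is the product of
#' fascicle length and the cosine of the pennation angle.
#'
#' @param fascicle_length_mm fascicle length(s), mm.
#' @param pennation_deg pennation angle(s), degrees, in \[0, 90).
#' @return muscle length(s), mm.
#' @export
muscle_length <- function(fascicle_length_mm, pennation_deg) {
  if (any(pennation_deg < 0 | pennation_deg >= 90))
    af_stop("pennation must lie in [0, 90) degrees", "archforce_domain_error")
  fascicle_length_mm * cos(deg2rad(pennation_deg))
}

#' Locate the iso-velocity phase common to all isokinetic trials
#'
#' Finds the times at which the knee angle crosses the window's start and
#' end angles (defaults 80 and 50 deg flexion, the constant-velocity phase
#' shared by all isokinetic speeds) during extension, by linear
#' interpolation between the bracketing samples. If a crossing occurs more
#' than once, the first extension crossing is used.
#'
#' @param trace a [torque_trace()] (or any data frame with `time_s` and
#'   `angle_deg`).
#' @param angles window angles, degrees flexion, from start to end of the
#'   extension (start > end).
#' @return a list of class `"isovelocity_window"` with `start_angle`,
#'   `end_angle`, `start_time`, `end_time`.
#' @export
isovelocity_window <- function(trace, angles = c(80, 50)) {
  t <- trace$time_s; a <- trace$angle_deg
  cross_down <- function(level) {
    i <- which(a[-length(a)] > level & a[-1] <= level)
    if (length(i) == 0L)
      af_stop(sprintf("angle never crosses %g deg during extension", level),
              "archforce_trial_error")
    i <- i[1]
    t[i] + (a[i] - level) / (a[i] - a[i + 1]) * (t[i + 1] - t[i])
  }
  t0 <- cross_down(angles[1])
  t1 <- cross_down(angles[2])
  if (t1 <= t0)
    af_stop("iso-velocity window has non-positive duration",
            "archforce_trial_error")
  structure(list(start_angle = angles[1], end_angle = angles[2],
                 start_time = t0, end_time = t1),
            class = "isovelocity_window")
}

#' Peak values inside a window
#'
#' Returns the maximum of each value column within the window; each column
#' gets its own peak (peak force and peak velocity need not be
#' simultaneous). By default the peak is the largest sample; with
#' `refine = TRUE` a parabola through the peak sample and its neighbours
#' refines the value, which removes the sampling-grid bias for smooth
#' signals.
#'
#' @param series a data frame with a `time_s` column and one or more value
#'   columns.
#' @param window an [isovelocity_window()] (or list with `start_time`,
#'   `end_time`).
#' @param refine logical; quadratic refinement of the peak value.
#' @return named numeric vector of peak values, one per value column.
#' @export
peak_in_window <- function(series, window, refine = FALSE) {
  keep <- series$time_s >= window$start_time & series$time_s <= window$end_time
  if (!any(keep))
    af_stop("no samples inside the window", "archforce_trial_error")
  cols <- setdiff(names(series), "time_s")
  idx <- which(keep)
  vapply(cols, function(cn) {
    y <- series[[cn]]
    j <- idx[which.max(y[idx])]
    if (!refine || j <= 1L || j >= length(y)) return(y[j])
    y0 <- y[j - 1]; y1 <- y[j]; y2 <- y[j + 1]
    den <- y0 - 2 * y1 + y2
    if (den >= 0) return(y1)                       # not a local parabolic max
    dx <- 0.5 * (y0 - y2) / den                    # vertex offset in samples
    if (!is.finite(dx) || abs(dx) > 1) return(y1)  # distrust: flat/noisy apex
    y1 - (y2 - y0)^2 / (8 * den)
  }, numeric(1))
}

# window length (odd) for Savitzky-Golay operators on a fascicle series,
# scaled to the iso-velocity phase duration: half-width
# min(0.9 * phase, 0.3 s), so the span never reaches back across the
# motion-onset kink from inside the phase
sg_window <- function(series, phase_duration) {
  dt <- median(diff(series$time_s))
  half <- max(2L, floor(min(0.9 * phase_duration, 0.3) / dt))
  n <- 2L * half + 1L
  min(n, if (nrow(series) %% 2L == 1L) nrow(series) else nrow(series) - 1L)
}

# Savitzky-Golay smoothing (local quadratic fits): polynomial-preserving,
# so linear length-time segments (constant-velocity phases) pass through
# exactly
smooth_fascicle_series <- function(series, phase_duration) {
  n <- sg_window(series, phase_duration)
  if (n < 5L) return(series)
  for (cn in intersect(c("fascicle_length_mm", "pennation_deg"), names(series)))
    series[[cn]] <- as.numeric(signal::sgolayfilt(series[[cn]], p = 2, n = n))
  series
}

# shortening velocity by the Savitzky-Golay derivative (slope of the local
# quadratic fit): statistically far more efficient on frame-wise noise than
# differencing a smoothed series, and exact wherever length is locally
# quadratic in time -- in particular on the constant-velocity phase.
# The span is 1.5x the phase duration: for an isokinetic motion whose
# constant-velocity segment extends beyond the common window on both
# sides, at least one window-interior centre then has a kink-free span,
# and a local slope whose span does cross a velocity kink always lies
# between the two segment slopes, so the windowed peak still comes from
# the kink-free centres
sg_vel_span <- function(dt, phase_duration, n_samples) {
  nmax <- if (n_samples %% 2L == 1L) n_samples else n_samples - 1L
  min(2L * max(2L, floor(1.5 * phase_duration / dt)) + 1L, nmax)
}

sgolay_velocity <- function(series, phase_duration) {
  dt <- median(diff(series$time_s))
  n <- sg_vel_span(dt, phase_duration, nrow(series))
  if (n < 5L)
    return(fascicle_velocity(series))
  -as.numeric(signal::sgolayfilt(series$fascicle_length_mm,
                                 p = 2, n = n, m = 1, ts = dt))
}
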