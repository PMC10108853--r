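# Torque conditioning and conversion to muscle force.

#' Knee joint angle-dependent moment arm model
#'
#' Polynomial model of the knee-extensor (patellar tendon) moment arm as a
#' function of knee-flexion angle. The default coefficients describe a
#' quadratic that is positive and single-peaked over 0-110 deg flexion,
#' with values between 3.1 and 4.4 cm, the range reported for the patellar
#' tendon in cadaveric and imaging studies. The model is deliberately
#' configurable: moment-arm estimates differ between literature sources and
#' all downstream forces scale with this choice.
#'
#' @param coefficients polynomial coefficients in increasing order
#'   (intercept first); the polynomial is evaluated in knee-flexion degrees
#'   and returns metres.
#' @param angle_range valid angle range (deg) of the model.
#' @return An object of class `"moment_arm_model"`.
#' @export
#' @examples
#' ma <- moment_arm_model()
#' eval_moment_arm(ma, 60)   # ~ 0.043 m
moment_arm_model <- function(coefficients = c(0.035, 3.5e-4, -3.5e-6),
                             angle_range = c(0, 110)) {
  if (length(coefficients) < 1L || any(!is.finite(coefficients)))
    af_stop("moment arm coefficients must be finite", "archforce_config_error")
  m <- structure(list(coefficients = coefficients, angle_range = angle_range),
                 class = "moment_arm_model")
  grid <- seq(angle_range[1], angle_range[2], length.out = 200)
  if (any(eval_moment_arm(m, grid) <= 0))
    af_stop("moment arm must be positive over its valid range",
            "archforce_config_error")
  m
}

#' Evaluate a moment arm model
#'
#' @param ma a [moment_arm_model()].
#' @param angle_deg knee-flexion angle(s) in degrees.
#' @return moment arm(s) in metres.
#' @export
eval_moment_arm <- function(ma, angle_deg) {
  rng <- ma$angle_range
  if (any(angle_deg < rng[1] - 1e-9 | angle_deg > rng[2] + 1e-9))
    af_stop(sprintf("angle outside moment-arm model range [%g, %g] deg",
                    rng[1], rng[2]), "archforce_model_error")
  out <- numeric(length(angle_deg))
  for (k in seq_along(ma$coefficients))
    out <- out + ma$coefficients[k] * angle_deg^(k - 1)
  out
}

#' Muscle force share model
#'
#' The fraction of total knee-extension force attributed to one muscle,
#' based on its physiological cross-sectional area (PCSA) relative to the
#' whole synergist group. The default of 0.35 for the vastus lateralis is
#' consistent with published PCSA fractions and with the ratio of the
#' cohort-mean vastus lateralis fascicle force to the cohort-mean knee
#' extension force (1856 / 5295 = 0.3506).
#'
#' @param pcsa_share fraction in (0, 1).
#' @return An object of class `"muscle_share_model"`.
#' @export
muscle_share_model <- function(pcsa_share = 0.35) {
  if (!is.numeric(pcsa_share) || length(pcsa_share) != 1L ||
      !is.finite(pcsa_share) || pcsa_share <= 0 || pcsa_share >= 1)
    af_stop("pcsa_share must lie strictly between 0 and 1",
            "archforce_config_error")
  structure(list(pcsa_share = pcsa_share), class = "muscle_share_model")
}

# one causal pass of an IIR filter (b, a), started from the steady state
# that corresponds to a constant input equal to the first sample -- this is
# what makes the bidirectional filter exact on constant signals and free of
# start-up transients on smooth ones
iir_pass <- function(x, b, a) {
  nb <- length(b)
  x0 <- x[1]
  xx <- c(rep(x0, nb - 1L), x)
  z <- as.numeric(stats::filter(xx, b, method = "convolution", sides = 1))
  z <- z[nb:length(xx)]
  y0 <- x0 * sum(b) / sum(a)
  as.numeric(stats::filter(z, -a[-1], method = "recursive",
                           init = rep(y0, length(a) - 1L)))
}

#' Zero-phase low-pass filtering of a torque trace
#'
#' Applies a bi-directional (forward-backward) Butterworth low-pass filter
#' to the torque channel. The forward-backward scheme doubles the effective
#' magnitude response (gain exactly 1/2 at the cutoff for order 2) and
#' cancels phase distortion, so torque peaks are not delayed. Edges are
#' handled by odd-reflection padding of about three filter time constants
#' combined with steady-state initial conditions, so constant traces pass
#' through unchanged.
#'
#' With `twicing > 0` the smoother `S` is applied with that many
#' residual-feedback iterations (Tukey's twicing for `twicing = 1`, van
#' Cittert iteration in general): the smoothed residual is added back, so
#' the effective operator is `I - (I - S)^(twicing + 1)`. Each iteration
#' cancels one further order of the smoother's attenuation of sharp
#' in-band features, at the cost of somewhat less out-of-band noise
#' suppression. The pipeline uses two iterations when reading peak forces
#' from fast force transients, which a plain low-pass measurably clips.
#'
#' @param trace a [torque_trace()].
#' @param cutoff cutoff frequency in Hz (default 20).
#' @param order filter order of each pass (default 2).
#' @param twicing number of residual-feedback iterations (0 = plain
#'   zero-phase filtering; `TRUE` counts as 1).
#' @return the filtered trace (same class and attributes).
#' @export
#' @examples
#' tr <- torque_trace(seq(0, 1, 1e-3), rep(60, 1001), rep(50, 1001))
#' f <- filter_torque(tr)
#' max(abs(f$torque_Nm - 50))  # ~ 0
filter_torque <- function(trace, cutoff = 20, order = 2, twicing = 0) {
  fs <- trace_fs(trace)
  if (fs <= 2 * cutoff)
    af_stop("sampling rate must exceed twice the cutoff frequency",
            "archforce_signal_error")
  x <- trace$torque_Nm
  n <- length(x)
  if (n <= 3L * order + 1L)
    af_stop("trace shorter than the filter warm-up length",
            "archforce_signal_error")
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  npad <- min(n - 1L, max(3L * order, ceiling(3 * fs / cutoff)))
  smooth_once <- function(x) {
    pre <- 2 * x[1] - x[(npad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xp <- c(pre, x, post)
    xp <- iir_pass(xp, bf$b, bf$a)
    xp <- rev(iir_pass(rev(xp), bf$b, bf$a))
    xp[(npad + 1L):(npad + n)]
  }
  k <- as.integer(twicing)
  d <- x
  for (j in seq_len(k + 1L)) d <- d - smooth_once(d)
  trace$torque_Nm <- x - d    # (I - (I - S)^(k+1)) x
  trace
}

#' Subtract passive (gravity + elastic) torque, matched by joint angle
#'
#' The torque recorded during a slow passive movement through the range of
#' motion contains the gravitational moment of the limb plus passive elastic
#' torque. Both depend on joint angle, not on time, so the correction
#' interpolates the passive torque at each knee angle of the active trial
#' and subtracts it.
#'
#' @param active a [torque_trace()] of an active trial.
#' @param passive a [torque_trace()] of the passive movement; its angle
#'   range must cover the active trial's angles.
#' @return the corrected active trace.
#' @export
correct_passive <- function(active, passive) {
  pv <- approx(x = passive$angle_deg, y = passive$torque_Nm,
               xout = active$angle_deg, ties = mean, rule = 1)$y
  if (any(is.na(pv)))
    af_stop("active trial angles outside the passive trial's coverage",
            "archforce_extrapolation_error")
  active$torque_Nm <- active$torque_Nm - pv
  active
}

#' Knee extension force from torque and moment arm
#'
#' Force is the quotient of the joint torque and the angle-dependent moment
#' arm.
#'
#' @param torque_Nm torque value(s), N*m.
#' @param angle_deg knee-flexion angle(s), degrees.
#' @param ma a [moment_arm_model()].
#' @return force in N.
#' @export
#' @examples
#' knee_extension_force(150, 60, moment_arm_model(c(0.05), c(0, 110)))  # 3000
knee_extension_force <- function(torque_Nm, angle_deg, ma = moment_arm_model()) {
  arm <- eval_moment_arm(ma, angle_deg)
  if (any(arm <= 0))
    af_stop("moment arm is non-positive at a requested angle",
            "archforce_model_error")
  torque_Nm / arm
}

#' Single-muscle force from knee extension force
#'
#' Attribution of knee-extension force to one muscle by its PCSA fraction.
#'
#' @param knee_force_N knee extension force(s), N (non-negative).
#' @param share a [muscle_share_model()] or a bare fraction in (0, 1).
#' @return muscle force in N.
#' @export
vastus_lateralis_force <- function(knee_force_N, share = muscle_share_model()) {
  if (is.numeric(share)) share <- muscle_share_model(share)
  if (any(knee_force_N < 0))
    af_stop("knee extension force must be non-negative",
            "archforce_input_error")
  share$pcsa_share * knee_force_N
}

#' Select the best of repeated attempts
#'
#' Given repeated attempts of the same condition, returns the trial with the
#' highest peak torque; ties are broken by first occurrence.
#'
#' @param trials a list of [torque_trace()] objects.
#' @return the selected trace.
#' @export
select_best_attempt <- function(trials) {
  if (length(trials) == 0L)
    af_stop("no trials supplied", "archforce_input_error")
  peaks <- vapply(trials, function(tr) max(tr$torque_Nm), numeric(1))
  trials[[which.max(peaks)]]
}
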