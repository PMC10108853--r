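# Contractile models: force-length and Hill force-velocity curves, their
# bounded least-squares fits, and the derived per-participant force summary.

#' Evaluate the force-length model
#'
#' The active force-length relation
#' `F = force_max * exp(-abs(((L / L0)^b - 1) / s)^rho)`
#' with `rho = 2` by default: a skewed bell with its peak exactly at
#' `L = L0`, skewness `b` and width `s`.
#'
#' @param L fascicle length(s), mm (positive).
#' @param params list or [force_length_fit] with `force_max` (N), `L0`
#'   (mm), `b`, `s`, and optionally `rho` (default 2).
#' @return force in N.
#' @export
#' @examples
#' p <- list(force_max = 1000, L0 = 100, b = 2, s = 0.5)
#' eval_force_length(120, p)  # 1000 * exp(-0.88^2) = 461.0 N
eval_force_length <- function(L, params) {
  if (any(L <= 0))
    af_stop("fascicle length must be positive", "archforce_domain_error")
  rho <- params$rho %||% 2
  params$force_max *
    exp(-abs(((L / params$L0)^params$b - 1) / params$s)^rho)
}

#' Fit the force-length model
#'
#' Nonlinear least squares over `(force_max, L0, b, s)` by bounded
#' Levenberg-Marquardt. Initial values are data-driven: `L0` at the length
#' of the largest observed force, `force_max` at 1.05 times the largest
#' force, `b = 1`, `s = 0.5`. Because the theoretical peak usually falls
#' between measured lengths, the fitted `force_max` may exceed every
#' observed force.
#'
#' @param L,F paired fascicle lengths (mm) and forces (N); at least 4
#'   points.
#' @param rho shape exponent of the model (default 2).
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return an object of class `"force_length_fit"`: the parameters,
#'   fitted values and residuals.
#' @export
fit_force_length <- function(L, F, rho = 2,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, ftol = 1e-15, ptol = 1e-15)) {
  if (length(L) != length(F))
    af_stop("L and F must have equal length", "archforce_input_error")
  if (length(L) < 4L)
    af_stop("at least 4 (L, F) points are needed for 4 parameters",
            "archforce_input_error")
  if (any(L <= 0) || any(!is.finite(F)))
    af_stop("invalid force-length data", "archforce_input_error")
  start <- c(force_max = 1.05 * max(F), L0 = L[which.max(F)], b = 1, s = 0.5)
  lower <- c(0.2 * max(F), 0.4 * min(L), 0.05, 0.01)
  upper <- c(10 * max(F), 2.5 * max(L), 10, 5)
  resid_fn <- function(p) {
    F - eval_force_length(L, list(force_max = p[1], L0 = p[2],
                                  b = p[3], s = p[4], rho = rho))
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, control = control)
  if (fit$info %in% c(0, 9))
    af_stop(sprintf("force-length fit did not converge: %s", fit$message),
            "archforce_fit_error")
  p <- fit$par
  out <- list(force_max = unname(p[1]), L0 = unname(p[2]),
              b = unname(p[3]), s = unname(p[4]), rho = rho,
              fitted = F - fit$fvec, residuals = fit$fvec,
              data = data.frame(L = L, F = F),
              rss = sum(fit$fvec^2), info = fit$info)
  class(out) <- "force_length_fit"
  out
}

#' @export
print.force_length_fit <- function(x, ...) {
  cat(sprintf(
    "Force-length fit: force_max = %.1f N, L0 = %.1f mm, b = %.3f, s = %.3f (rho = %g, RSS = %.3g)\n",
    x$force_max, x$L0, x$b, x$s, x$rho, x$rss))
  invisible(x)
}

#' @export
coef.force_length_fit <- function(object, ...) {
  c(force_max = object$force_max, L0 = object$L0, b = object$b, s = object$s)
}

#' Evaluate the Hill force-velocity hyperbola
#'
#' `F = force_max * (1 - v / vmax) / (1 + G * v / vmax)` for shortening
#' velocities `0 <= v <= vmax`. `G` is the dimensionless curvature: larger
#' `G` means a more curved relation, i.e. greater force loss at moderate
#' velocities. Extrapolation beyond `vmax` is refused.
#'
#' @param v shortening velocity (same units as `vmax`).
#' @param params list or [force_velocity_fit] with `force_max`, `vmax`, `G`.
#' @return force in N.
#' @export
#' @examples
#' eval_force_velocity(5, list(force_max = 1000, vmax = 10, G = 6))  # 125 N
eval_force_velocity <- function(v, params) {
  if (any(v < 0 | v > params$vmax))
    af_stop("velocity outside [0, vmax]: extrapolation refused",
            "archforce_domain_error")
  phi <- v / params$vmax
  params$force_max * (1 - phi) / (1 + params$G * phi)
}

#' Fit the Hill force-velocity curve
#'
#' Least squares over `(vmax, G)` with `force_max` held fixed at the value
#' from the force-length fit. The curvature is constrained to the open
#' interval (3, 9) by hard box bounds (with a 1e-6 margin); `vmax` is
#' unconstrained beyond being larger than the fastest observed velocity.
#' A solution within 1e-4 of a curvature bound is flagged
#' (`bound_hit = TRUE`) and reported with a warning, not an error.
#'
#' @param v,F paired shortening velocities and forces (at least 2 points).
#' @param force_max fixed maximum isometric force (N).
#' @param g_bounds curvature bounds (default `c(3, 9)`).
#' @param weights optional non-negative observation weights (e.g. inverse
#'   effective variances when the measurement error differs between
#'   speeds); `NULL` for ordinary least squares. Weights do not change an
#'   interpolating (zero-residual) solution.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return an object of class `"force_velocity_fit"` with `vmax` (in the
#'   units of `v`), `G`, `force_max`, `bound_hit`, fitted values and
#'   residuals.
#' @export
fit_force_velocity <- function(v, F, force_max, g_bounds = c(3, 9),
                               weights = NULL,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-15, ptol = 1e-15)) {
  if (length(v) != length(F))
    af_stop("v and F must have equal length", "archforce_input_error")
  if (length(v) < 2L)
    af_stop("at least 2 (v, F) points are needed for 2 parameters",
            "archforce_input_error")
  if (all(F >= force_max))
    af_stop("all forces at or above force_max: no descending limb to fit",
            "archforce_fit_error")
  if (is.null(weights)) weights <- rep(1, length(v))
  if (length(weights) != length(v) || any(!is.finite(weights)) ||
      any(weights < 0) || all(weights == 0))
    af_stop("weights must be non-negative with at least one positive",
            "archforce_input_error")
  sw <- sqrt(weights / mean(weights))
  eps <- 1e-6
  lower <- c(max(v) * (1 + 1e-9), g_bounds[1] + eps)
  upper <- c(1e6 * max(v), g_bounds[2] - eps)
  resid_fn <- function(p)
    sw * (F - eval_force_velocity(v, list(force_max = force_max,
                                          vmax = p[1], G = p[2])))
  # the (vmax, G) surface has a long curved valley in which plain
  # Levenberg-Marquardt from a fixed start can stall against the curvature
  # bound; profile G on a grid, minimising over log(vmax) for each, then
  # polish the best profile point with the bounded 2-parameter fit
  rss_vmax <- function(G) {
    o <- optimise(function(lv) {
      sum((sw * (F - force_max * (1 - v / exp(lv)) /
                   (1 + G * v / exp(lv))))^2)
    }, interval = log(c(lower[1], upper[1])), tol = 1e-12)
    c(vmax = exp(o$minimum), rss = o$objective)
  }
  g_grid <- seq(lower[2], upper[2], length.out = 31)
  prof <- vapply(g_grid, rss_vmax, numeric(2))
  i_best <- which.min(prof["rss", ])
  start <- c(vmax = unname(prof["vmax", i_best]), G = g_grid[i_best])
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, control = control)
  if (fit$info %in% c(0, 9))
    af_stop(sprintf("force-velocity fit did not converge: %s", fit$message),
            "archforce_fit_error")
  G <- unname(fit$par[2])
  bound_hit <- min(G - g_bounds[1], g_bounds[2] - G) < 1e-4
  if (bound_hit)
    warning(sprintf("force-velocity curvature at its bound (G = %.4f)", G),
            call. = FALSE)
  out <- list(force_max = force_max, vmax = unname(fit$par[1]), G = G,
              bound_hit = bound_hit, weights = weights,
              fitted = F - fit$fvec / sw, residuals = fit$fvec / sw,
              data = data.frame(v = v, F = F),
              rss = sum(fit$fvec^2), info = fit$info)
  class(out) <- "force_velocity_fit"
  out
}

#' @export
print.force_velocity_fit <- function(x, ...) {
  cat(sprintf(
    "Force-velocity fit: vmax = %.3g, G = %.3f%s (force_max fixed at %.1f N, RSS = %.3g)\n",
    x$vmax, x$G, if (x$bound_hit) " [at bound]" else "", x$force_max, x$rss))
  invisible(x)
}

#' @export
coef.force_velocity_fit <- function(object, ...) {
  c(vmax = object$vmax, G = object$G)
}

#' Normalised slope of the force-velocity curve between two velocities
#'
#' The decline in normalised force (force divided by `force_max`) per unit
#' shortening velocity, between the fascicle velocities measured during the
#' slowest and the fastest isokinetic condition, both evaluated on the
#' fitted curve. A simplified, noise-robust surrogate of the curvature
#' parameter `G`; negative for a decreasing curve. Velocity units follow
#' the units of the fit (the slope is "per velocity unit").
#'
#' @param fv a [force_velocity_fit] (or list with `force_max`, `vmax`, `G`).
#' @param v_slow,v_fast the two velocities, `v_slow < v_fast <= vmax`.
#' @return the slope, normalised force per velocity unit.
#' @export
#' @examples
#' fv <- list(force_max = 1000, vmax = 100, G = 5)
#' force_slope(fv, 10, 80)  # (0.04 - 0.60) / 70 = -0.008
force_slope <- function(fv, v_slow, v_fast) {
  if (v_slow >= v_fast)
    af_stop("v_slow must be below v_fast", "archforce_input_error")
  f1 <- eval_force_velocity(v_slow, fv) / fv$force_max
  f2 <- eval_force_velocity(v_fast, fv) / fv$force_max
  (f2 - f1) / (v_fast - v_slow)
}

#' Per-participant force summary
#'
#' Assembles the force measures derived from the fitted curves and the
#' measured peaks: the theoretical maximum force `force_max` and optimal
#' length `L0` (force-length fit), the curvature `G` and maximum shortening
#' velocity (force-velocity fit), the measured peak force of the fastest
#' isokinetic condition (`force_iso400`), and the normalised force-velocity
#' slope between the slowest and fastest measured fascicle velocities
#' (reported per cm/s and per optimal length/s).
#'
#' @param fl a [force_length_fit].
#' @param fv a [force_velocity_fit] whose velocities are in mm/s.
#' @param peaks data frame with columns `speed_deg_s`, `peak_force_N`,
#'   `peak_velocity_mm_s`, one row per isokinetic speed; must include the
#'   fastest (400 deg/s) condition.
#' @param share a [muscle_share_model()] used to also express the maximum
#'   force at the single-muscle (fascicle) level.
#' @param fastest_speed,slowest_speed nominal speeds defining
#'   `force_iso400` and the slope (defaults 400 and 50 deg/s).
#' @return a one-row data frame of class `"force_summary"`.
#' @export
summarise_forces <- function(fl, fv, peaks, share = muscle_share_model(),
                             fastest_speed = 400, slowest_speed = 50) {
  if (is.numeric(share)) share <- muscle_share_model(share)
  i_fast <- which(peaks$speed_deg_s == fastest_speed)
  i_slow <- which(peaks$speed_deg_s == slowest_speed)
  if (length(i_fast) != 1L)
    af_stop(sprintf("missing the %g deg/s isokinetic condition",
                    fastest_speed), "archforce_summary_error")
  if (length(i_slow) != 1L)
    af_stop(sprintf("missing the %g deg/s isokinetic condition",
                    slowest_speed), "archforce_summary_error")
  slope_mm <- force_slope(fv, peaks$peak_velocity_mm_s[i_slow],
                          peaks$peak_velocity_mm_s[i_fast])
  out <- data.frame(
    force_max = fl$force_max,
    force_iso400 = peaks$peak_force_N[i_fast],
    G = fv$G,
    L0 = fl$L0,
    vmax_mm_s = fv$vmax,
    vmax_L0_s = fv$vmax / fl$L0,
    force_slope_cm_s = slope_mm * 10,       # per cm/s
    force_slope_L0_s = slope_mm * fl$L0,    # per optimal length/s
    vl_force_max = share$pcsa_share * fl$force_max,
    fv_bound_hit = fv$bound_hit)
  class(out) <- c("force_summary", "data.frame")
  out
}
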