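# Synthetic cohort: virtual participants with known ground-truth
# contractile properties, and simulation of every recording the pipeline
# consumes (dynamometer trials, fascicle time series, probe scenes).

#' Default ground-truth parameter distributions
#'
#' Truncated normal distributions (mean, sd, lower, upper) for the
#' ground-truth muscle parameters of a simulated cohort. Means and SDs
#' follow printed cohort statistics for the vastus lateralis: theoretical
#' maximum knee-extension force 5295 +/- 1504 N, optimal fascicle length
#' 105 +/- 17 mm, maximum shortening velocity 17.5 +/- 10.5 optimal
#' lengths/s, force-velocity curvature G = 6.1 +/- 2.7 (truncated inside
#' the physiological band (3, 9)), and Table-1-style architecture
#' statistics per measurement condition. Truncation bounds are
#' physiological limits.
#'
#' @return a named list of length-4 numeric vectors
#'   `c(mean, sd, lower, upper)`.
#' @export
default_parameter_distributions <- function() {
  list(
    force_max = c(mean = 5295, sd = 1504, lower = 2000, upper = 9500),
    L0        = c(mean = 105,  sd = 17,   lower = 70,   upper = 145),
    b         = c(mean = 1.5,  sd = 0.3,  lower = 0.8,  upper = 2.5),
    s         = c(mean = 0.45, sd = 0.08, lower = 0.25, upper = 0.75),
    vmax_L0_s = c(mean = 17.5, sd = 10.5, lower = 4.5,  upper = 45),
    G         = c(mean = 6.1,  sd = 2.7,  lower = 3.2,  upper = 8.8),
    len_rest0  = c(mean = 82.3,  sd = 9.5,  lower = 55, upper = 115),
    len_rest60 = c(mean = 120.4, sd = 12.7, lower = 85, upper = 160),
    len_mvc60  = c(mean = 96.7,  sd = 18.1, lower = 60, upper = 150),
    pen_rest0  = c(mean = 15.7, sd = 2.4, lower = 8,  upper = 28),
    pen_rest60 = c(mean = 10.9, sd = 1.6, lower = 6,  upper = 20),
    pen_mvc60  = c(mean = 14.5, sd = 2.7, lower = 8,  upper = 28)
  )
}

#' Simulation configuration for a synthetic cohort
#'
#' Defines the study conditions the generator emulates: cohort size,
#' isometric test angles (100-50 deg knee flexion in 10 deg steps),
#' isokinetic speeds (50/100/200/300/400 deg/s over a 110 deg -> 0 deg
#' range of motion), sampling rates, and additive measurement noise.
#'
#' The fascicle-length vs knee-angle mapping under maximal contraction is
#' `L(theta) = L0 * (1 + length_angle_slope * (theta - optimal_angle))`
#' with `optimal_angle = 60` deg, so fascicles are at optimal length at the
#' near-optimal test angle. The default slope 0.00795 per degree gives a
#' measured peak fascicle velocity of ~3.2 optimal lengths/s in the fastest
#' (400 deg/s) condition which, combined with the default curvature and
#' vmax distributions, reproduces the observed ratio of fastest-condition
#' force to maximum force (~0.39).
#'
#' @param n_participants cohort size (>= 2); default 21.
#' @param seed integer seed; every cohort drawn with the same config and
#'   seed is identical.
#' @param sampling_rate dynamometer sampling rate, Hz.
#' @param fascicle_rate ultrasound fascicle-tracking frame rate, Hz.
#' @param noise_torque_sd additive white torque noise, N*m.
#' @param noise_length_sd additive fascicle-length noise per frame, mm.
#' @param noise_pennation_sd additive pennation noise per frame, deg.
#' @param isometric_angles isometric test angles, deg knee flexion.
#' @param isokinetic_speeds isokinetic speeds, deg/s.
#' @param parameter_distributions see [default_parameter_distributions()].
#' @param pcsa_share PCSA fraction of knee-extension force attributed to
#'   the vastus lateralis.
#' @param length_angle_slope fascicle-length/knee-angle slope under
#'   contraction, per degree (in units of L0).
#' @param optimal_angle knee angle (deg) at which contracting fascicles are
#'   at optimal length.
#' @param moment_arm the [moment_arm_model()] used to turn muscle force
#'   into joint torque (and back, in the analysis).
#' @param passive parameters of the passive torque model
#'   `amp * exp(rate * theta) - gravity * sin(theta + 15 deg)` (N*m).
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_participants = 21, seed = 1,
                              sampling_rate = 1000, fascicle_rate = 100,
                              noise_torque_sd = 2, noise_length_sd = 1,
                              noise_pennation_sd = 0.5,
                              isometric_angles = c(100, 90, 80, 70, 60, 50),
                              isokinetic_speeds = c(50, 100, 200, 300, 400),
                              parameter_distributions =
                                default_parameter_distributions(),
                              pcsa_share = 0.35,
                              length_angle_slope = 0.00795,
                              optimal_angle = 60,
                              moment_arm = moment_arm_model(),
                              passive = list(amp = 0.5, rate = 0.025,
                                             gravity = 10)) {
  if (n_participants < 2)
    af_stop("n_participants must be at least 2", "archforce_config_error")
  if (sampling_rate <= 0 || fascicle_rate <= 0)
    af_stop("sampling rates must be positive", "archforce_config_error")
  if (noise_torque_sd < 0 || noise_length_sd < 0 || noise_pennation_sd < 0)
    af_stop("noise standard deviations must be non-negative",
            "archforce_config_error")
  if (pcsa_share <= 0 || pcsa_share >= 1)
    af_stop("pcsa_share must lie strictly in (0, 1)",
            "archforce_config_error")
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    sampling_rate = sampling_rate, fascicle_rate = fascicle_rate,
    noise_torque_sd = noise_torque_sd, noise_length_sd = noise_length_sd,
    noise_pennation_sd = noise_pennation_sd,
    isometric_angles = isometric_angles,
    isokinetic_speeds = sort(isokinetic_speeds),
    parameter_distributions = parameter_distributions,
    pcsa_share = pcsa_share,
    length_angle_slope = length_angle_slope,
    optimal_angle = optimal_angle,
    moment_arm = moment_arm, passive = passive),
    class = "simulation_config")
}

# passive (gravity + elastic) torque as a smooth function of knee angle
sim_passive_torque <- function(theta, passive) {
  passive$amp * exp(passive$rate * theta) -
    passive$gravity * sin(deg2rad(theta + 15))
}

# fascicle length (mm) at knee angle theta under maximal contraction
sim_length_mvc <- function(theta, truth, config) {
  truth$L0 * (1 + config$length_angle_slope * (theta - config$optimal_angle))
}

# fascicle length at rest (residual slack, less angle-sensitive)
sim_length_rest <- function(theta, truth, config) {
  truth$L0 * (0.85 + 0.005 * theta)
}

# C1-continuous activation ramp (smootherstep): kink-free torque onsets so
# the zero-phase filter does not ring at the ramp corners
sim_ramp <- function(t, t_on, t_full) {
  u <- pmin(1, pmax(0, (t - t_on) / (t_full - t_on)))
  u * u * (3 - 2 * u)
}

sim_pennation <- function(length_mm, thickness_mm) {
  rad2deg(asin(pmin(0.95, thickness_mm / length_mm)))
}

# one ground-truth participant: contractile parameters plus architecture
# triples. Pennation co-varies with strength and condition-wise fascicle
# length with optimal length; thickness is derived as L*sin(pennation) so
# that straight-fascicle scene reconstruction closes the loop exactly.
sim_draw_truth <- function(id, config) {
  pd <- config$parameter_distributions
  draw1 <- function(nm) rtruncnorm(1, pd[[nm]]["mean"], pd[[nm]]["sd"],
                                   pd[[nm]]["lower"], pd[[nm]]["upper"])
  force_max <- draw1("force_max")
  L0 <- draw1("L0")
  z_F <- (force_max - pd$force_max["mean"]) / pd$force_max["sd"]
  z_L <- (L0 - pd$L0["mean"]) / pd$L0["sd"]
  corr_draw <- function(nm, z, rho) {
    x <- pd[[nm]]["mean"] + pd[[nm]]["sd"] *
      (rho * z + sqrt(1 - rho^2) * rnorm(1))
    unname(pmin(pd[[nm]]["upper"], pmax(pd[[nm]]["lower"], x)))
  }
  arch <- function(cond, len_nm, pen_nm) {
    len <- corr_draw(len_nm, z_L, 0.6)
    pen <- corr_draw(pen_nm, z_F, 0.6)
    architecture_measure(cond, len, pen, len * sin(deg2rad(pen)))
  }
  list(id = id,
       force_max_true = unname(force_max), L0_true = unname(L0),
       b_true = unname(draw1("b")), s_true = unname(draw1("s")),
       vmax_true_L0_s = unname(draw1("vmax_L0_s")), G_true = unname(draw1("G")),
       pcsa_share = config$pcsa_share,
       rest0_arch = arch("REST_0", "len_rest0", "pen_rest0"),
       rest60_arch = arch("REST_60", "len_rest60", "pen_rest60"),
       mvc60_arch = arch("MVC_60", "len_mvc60", "pen_mvc60"))
}

# simulated active fascicle force (knee-extension level) at length L (mm)
# and normalised shortening velocity phi = v / vmax
sim_active_force <- function(L, phi, truth) {
  fl <- eval_force_length(L, list(force_max = truth$force_max_true,
                                  L0 = truth$L0_true, b = truth$b_true,
                                  s = truth$s_true))
  fl * (1 - phi) / (1 + truth$G_true * phi)
}

sim_fascicle_frame <- function(t, L, pen, config) {
  n <- length(t)
  data.frame(
    time_s = t,
    fascicle_length_mm = L + rnorm(n, 0, config$noise_length_sd),
    pennation_deg = pen + rnorm(n, 0, config$noise_pennation_sd))
}

sim_isometric_trial <- function(truth, angle, config) {
  dt <- 1 / config$sampling_rate
  t <- seq(0, 6, by = dt)
  a <- sim_ramp(t, 1, 3)
  Lm <- sim_length_mvc(angle, truth, config)
  Lr <- sim_length_rest(angle, truth, config)
  tq <- sim_passive_torque(angle, config$passive) +
    a * sim_active_force(Lm, 0, truth) *
      eval_moment_arm(config$moment_arm, angle) +
    rnorm(length(t), 0, config$noise_torque_sd)
  tf <- seq(0, 6, by = 1 / config$fascicle_rate)
  af <- sim_ramp(tf, 1, 3)
  Lf <- Lr + (Lm - Lr) * af
  pen <- sim_pennation(Lf, truth$mvc60_arch$thickness)
  list(participant_id = truth$id, mode = "isometric", nominal = angle,
       torque = torque_trace(t, rep(angle, length(t)), tq,
                             mode = "isometric", nominal = angle),
       fascicle = sim_fascicle_frame(tf, Lf, pen, config))
}

sim_isokinetic_trial <- function(truth, speed, config) {
  dt <- 1 / config$sampling_rate
  t_move <- 110 / speed
  t <- seq(0, 1 + t_move + 0.5, by = dt)
  theta <- pmax(0, pmin(110, 110 - speed * (t - 1)))
  # activation completes 0.4 s before the dynamometer releases, as in an
  # isokinetic pre-loading protocol: the muscle is at a steady maximal
  # state when the motion starts
  a <- sim_ramp(t, 0, 0.6)
  moving <- t > 1 & t < 1 + t_move
  phi <- ifelse(moving,
                config$length_angle_slope * speed / truth$vmax_true_L0_s, 0)
  Fk <- a * sim_active_force(sim_length_mvc(theta, truth, config), phi, truth)
  tq <- sim_passive_torque(theta, config$passive) +
    Fk * eval_moment_arm(config$moment_arm, theta) +
    rnorm(length(t), 0, config$noise_torque_sd)
  tf <- seq(0, max(t), by = 1 / config$fascicle_rate)
  thf <- pmax(0, pmin(110, 110 - speed * (tf - 1)))
  af <- sim_ramp(tf, 0, 0.6)
  Lmvc <- sim_length_mvc(thf, truth, config)
  Lf <- ifelse(tf <= 1,
               sim_length_rest(110, truth, config) +
                 (sim_length_mvc(110, truth, config) -
                    sim_length_rest(110, truth, config)) * af,
               Lmvc)
  pen <- sim_pennation(Lf, truth$mvc60_arch$thickness)
  list(participant_id = truth$id, mode = "isokinetic", nominal = speed,
       torque = torque_trace(t, theta, tq,
                             mode = "isokinetic", nominal = speed),
       fascicle = sim_fascicle_frame(tf, Lf, pen, config))
}

sim_passive_trial <- function(truth, config) {
  dt <- 1 / config$sampling_rate
  speed <- 30
  t <- seq(0, 1 + 110 / speed + 1, by = dt)
  theta <- pmax(0, pmin(110, 110 - speed * (t - 1)))
  tq <- sim_passive_torque(theta, config$passive) +
    rnorm(length(t), 0, config$noise_torque_sd)
  list(participant_id = truth$id, mode = "passive", nominal = NA_real_,
       torque = torque_trace(t, theta, tq, mode = "passive"))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n_participants` virtual participants from the configured
#' ground-truth distributions and simulates, for each, six isometric trials
#' (100-50 deg flexion), five isokinetic trials (50-400 deg/s over
#' 110 -> 0 deg), one passive movement, fascicle length/pennation time
#' series consistent with the participant's force-length and
#' force-velocity surface, and ultrasound probe scenes for the three
#' architecture conditions. Simulated torque is the passive (gravity +
#' elastic) component plus the active component (the participant's
#' force-length x force-velocity surface evaluated at the simulated
#' fascicle state, times the moment arm), plus Gaussian noise.
#'
#' Identical configurations and seeds give identical cohorts.
#'
#' @param config a [simulation_config()].
#' @return an object of class `"muscle_cohort"`: a list with `participants`
#'   (each carrying `truth`, `trials`, `scenes`) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_participants = 2, seed = 7,
#'                                             noise_torque_sd = 0,
#'                                             noise_length_sd = 0,
#'                                             noise_pennation_sd = 0))
generate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    af_stop("config must be a simulation_config()", "archforce_config_error")
  set.seed(config$seed)
  participants <- lapply(seq_len(config$n_participants), function(i)
    simulate_participant(config, id = sprintf("P%02d", i)))
  muscle_cohort(participants, config)
}

#' Simulate all recordings of one participant
#'
#' Generates the six isometric trials, five isokinetic trials, passive
#' movement and probe scenes for one participant. If no ground truth is
#' supplied, one is drawn from the configured distributions; supplying a
#' fixed `truth` and varying the RNG state gives noise replicates of the
#' same underlying muscle (the standard setup for estimator-error studies).
#'
#' @param config a [simulation_config()].
#' @param truth optional ground-truth list, e.g. from
#'   [representative_truth()] or a previous draw.
#' @param id participant identifier.
#' @return a participant list (`id`, `truth`, `trials`, `scenes`).
#' @export
simulate_participant <- function(config, truth = NULL, id = "P01") {
  if (is.null(truth)) truth <- sim_draw_truth(id, config)
  truth$id <- id
  trials <- c(
    lapply(config$isometric_angles, function(a)
      sim_isometric_trial(truth, a, config)),
    lapply(config$isokinetic_speeds, function(v)
      sim_isokinetic_trial(truth, v, config)),
    list(sim_passive_trial(truth, config)))
  names(trials) <- c(paste0("iso_", config$isometric_angles),
                     paste0("isok_", config$isokinetic_speeds),
                     "passive")
  scenes <- list(
    REST_0 = generate_panoramic_scene(truth$rest0_arch),
    REST_60 = generate_probe_scene(truth$rest60_arch),
    MVC_60 = generate_probe_scene(truth$mvc60_arch))
  list(id = id, truth = truth, trials = trials, scenes = scenes)
}

#' Ground truth at the distribution means
#'
#' A representative participant whose contractile parameters and
#' architecture sit exactly at the configured distribution means; useful
#' as the fixed truth of noise-replicate studies.
#'
#' @param config a [simulation_config()].
#' @param id participant identifier.
#' @return a ground-truth list as used by [simulate_participant()].
#' @export
representative_truth <- function(config = simulation_config(), id = "P01") {
  pd <- config$parameter_distributions
  m <- function(nm) unname(pd[[nm]]["mean"])
  arch <- function(cond, len_nm, pen_nm) {
    len <- m(len_nm); pen <- m(pen_nm)
    architecture_measure(cond, len, pen, len * sin(deg2rad(pen)))
  }
  list(id = id, force_max_true = m("force_max"), L0_true = m("L0"),
       b_true = m("b"), s_true = m("s"),
       vmax_true_L0_s = m("vmax_L0_s"), G_true = m("G"),
       pcsa_share = config$pcsa_share,
       rest0_arch = arch("REST_0", "len_rest0", "pen_rest0"),
       rest60_arch = arch("REST_60", "len_rest60", "pen_rest60"),
       mvc60_arch = arch("MVC_60", "len_mvc60", "pen_mvc60"))
}

#' Assemble participants into a cohort object
#'
#' @param participants list of participants from [simulate_participant()].
#' @param config the [simulation_config()] they were generated under.
#' @return a `"muscle_cohort"`.
#' @export
muscle_cohort <- function(participants, config) {
  structure(list(participants = participants, config = config),
            class = "muscle_cohort")
}

#' @export
print.muscle_cohort <- function(x, ...) {
  cat(sprintf("<muscle_cohort> %d participants, seed %d, %d trials each\n",
              length(x$participants), x$config$seed,
              length(x$participants[[1]]$trials)))
  invisible(x)
}

#' Synthesise dual-probe segmentation coordinates for one architecture
#'
#' Builds a coordinate-level ultrasound scene (no pixel data) for the
#' dual-transducer setup: in the muscle frame the deep aponeurosis runs
#' along y = 0, the superficial aponeurosis along y = thickness, and a
#' straight fascicle inserts on the deep aponeurosis inside the distal
#' field of view at the true pennation angle. Feature points are then
#' expressed in each probe's local image frame (the distal probe is the
#' reference; the proximal probe sits beyond the inter-probe gap and is
#' rotated by the holder's angulation). The proximal probe contributes the
#' superficial aponeurosis only, mirroring the use of proximal scans for
#' the upper aponeurosis.
#'
#' @param arch an [architecture_measure()]; the scene is constructed so
#'   that its true fascicle length and pennation equal `arch`'s values.
#' @param probe_geometry list with `field_width`, `field_depth`, `gap` (mm)
#'   and `angulation_deg` (the inter-probe tilt, default 5 deg).
#' @param frames optional named list of the two [probe_frame()]s, to place
#'   the probes elsewhere (any rigid placement reconstructs identically).
#' @param fascicle_x0 deep-insertion x of the fascicle within the distal
#'   field of view (mm).
#' @return a list with `segments` (local-frame point sets per probe),
#'   `frames`, `probe_geometry` and `truth` (= `arch`).
#' @export
generate_probe_scene <- function(arch,
                                 probe_geometry = list(field_width = 60,
                                                       field_depth = 40,
                                                       gap = 20,
                                                       angulation_deg = 5),
                                 frames = NULL, fascicle_x0 = 5) {
  th <- arch$thickness; pen <- arch$pennation
  if (th <= 0 || pen <= 0 || pen >= 90)
    af_stop("need thickness > 0 and 0 < pennation < 90 deg",
            "archforce_input_error")
  fw <- probe_geometry$field_width
  gap <- probe_geometry$gap
  if (fascicle_x0 < 0 || fascicle_x0 > fw - 2)
    af_stop("fascicle does not intersect the distal field of view",
            "archforce_geometry_error")
  if (is.null(frames)) {
    frames <- list(
      distal = probe_frame("distal", origin = c(0, 0), rotation_deg = 0,
                           field_width = fw,
                           field_depth = probe_geometry$field_depth),
      proximal = probe_frame("proximal", origin = c(fw + gap, 0),
                             rotation_deg = probe_geometry$angulation_deg,
                             field_width = fw,
                             field_depth = probe_geometry$field_depth))
  }
  # world-frame features (windows fixed by the nominal probe layout)
  xs_d <- seq(2, fw - 2, length.out = 8)
  xs_p <- seq(fw + gap + 2, 2 * fw + gap - 2, length.out = 8)
  dirv <- c(cos(deg2rad(pen)), sin(deg2rad(pen)))
  # fascicle points: the portion visible in the distal field of view
  t_exit <- (fw - 2 - fascicle_x0) / dirv[1]
  t_max <- min(arch$fascicle_length, t_exit)
  tt <- seq(0, t_max, length.out = 8)
  fas_w <- cbind(fascicle_x0 + tt * dirv[1], tt * dirv[2])
  world <- list(
    distal = list(
      deep_apo = cbind(xs_d, 0),
      superficial_apo = cbind(xs_d, th),
      fascicle = fas_w),
    proximal = list(superficial_apo = cbind(xs_p, th)))
  segments <- lapply(names(world), function(pid)
    lapply(world[[pid]], function(p) probe_world_to_local(frames[[pid]], p)))
  names(segments) <- names(world)
  list(segments = segments, frames = frames,
       probe_geometry = probe_geometry, truth = arch)
}

#' Synthesise a panoramic fragment scene for one architecture
#'
#' Coordinate-level counterpart of a panoramic (extended-field-of-view)
#' scan: parallel aponeuroses separated by the muscle thickness and
#' fascicle-fragment orientations equal to the true pennation in both the
#' deep and superficial region (the generator's fascicles are straight).
#'
#' @param arch an [architecture_measure()].
#' @param n_fragments fragments per region.
#' @return a list with `deep_fragments`, `superficial_fragments` (angles,
#'   deg), `deep_apo`, `superficial_apo` (point matrices) and `truth`.
#' @export
generate_panoramic_scene <- function(arch, n_fragments = 5) {
  th <- arch$thickness
  xs <- seq(-10, 110, length.out = 10)
  list(deep_fragments = rep(arch$pennation, n_fragments),
       superficial_fragments = rep(arch$pennation, n_fragments),
       deep_apo = cbind(xs, 0), superficial_apo = cbind(xs, th),
       truth = arch)
}

#' Reconstruct architecture from a dual-probe scene
#'
#' The analysis-side counterpart of [generate_probe_scene()]: fuses the
#' probe-local segmentations into the distal reference frame, extrapolates
#' the fascicle linearly to the superficial aponeurosis fitted from each
#' field of view separately, applies the shortest-candidate rule, and
#' measures pennation against the deep aponeurosis and thickness as the
#' mean inter-aponeurosis distance.
#'
#' @param scene a scene from [generate_probe_scene()] (or the same
#'   structure built from real segmentations).
#' @param condition condition label for the result.
#' @return an [architecture_measure()].
#' @export
reconstruct_dual_probe <- function(scene, condition = scene$truth$condition) {
  fused <- fuse_probe_frames(scene$segments, scene$frames)
  deep <- fused$distal$deep_apo
  fas <- fused$distal$fascicle
  cand <- vapply(list(fused$distal$superficial_apo,
                      fused$proximal$superficial_apo),
                 function(sup) {
                   tryCatch(
                     extrapolate_fascicle_length(fas, sup, deep)$fascicle_length,
                     archforce_error = function(e) NA_real_)
                 }, numeric(1))
  len <- shortest_candidate_length(cand)
  pen <- extrapolate_fascicle_length(fas, fused$distal$superficial_apo,
                                     deep)$pennation
  th <- muscle_thickness(rbind(fused$distal$superficial_apo,
                               fused$proximal$superficial_apo), deep)
  architecture_measure(condition, len, pen, th)
}
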