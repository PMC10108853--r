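# End-to-end orchestration: torque conditioning -> geometry -> kinematics
# -> curve fits -> work -> cohort statistics.

#' Analysis configuration for the pipeline
#'
#' @param filter_cutoff,filter_order Butterworth low-pass settings for the
#'   torque channel (defaults 20 Hz, order 2, bidirectional).
#' @param moment_arm a [moment_arm_model()].
#' @param pcsa_share PCSA fraction for single-muscle force.
#' @param window_angles iso-velocity window angles (deg flexion),
#'   start > end; the constant-velocity phase common to all isokinetic
#'   speeds.
#' @param rho force-length shape exponent.
#' @param g_bounds curvature bounds of the force-velocity fit.
#' @param smooth_fascicle logical; Savitzky-Golay smoothing (order 2,
#'   window scaled to the iso-velocity phase) of the fascicle series before
#'   differentiation. Quadratic-preserving, so constant-velocity shortening
#'   is untouched; strongly recommended for frame-wise noisy tracking.
#' @param refine_peaks logical; parabolic refinement of windowed peaks.
#' @param peak_twicing number of residual-feedback (twicing) iterations of
#'   the smoother used when reading isokinetic peak forces (see
#'   [filter_torque()]); preserves the amplitude of the fast force
#'   transient that a plain low-pass attenuates. 0 disables.
#' @param fastest_speed,slowest_speed nominal speeds for `force_iso400` and
#'   the normalised slope.
#' @param iso_hold_s duration (s) of the steady hold at the end of each
#'   isometric ramp-and-hold trial over which the plateau is read.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(filter_cutoff = 20, filter_order = 2,
                            moment_arm = moment_arm_model(),
                            pcsa_share = 0.35,
                            window_angles = c(80, 50),
                            rho = 2, g_bounds = c(3, 9),
                            smooth_fascicle = TRUE, refine_peaks = TRUE,
                            peak_twicing = 3,
                            fastest_speed = 400, slowest_speed = 50,
                            iso_hold_s = 2.5) {
  if (filter_cutoff <= 0 || filter_order < 1)
    af_stop("invalid filter settings", "archforce_config_error")
  if (window_angles[1] <= window_angles[2])
    af_stop("window start angle must exceed its end angle",
            "archforce_config_error")
  structure(list(filter_cutoff = filter_cutoff, filter_order = filter_order,
                 moment_arm = moment_arm,
                 share = muscle_share_model(pcsa_share),
                 window_angles = window_angles, rho = rho,
                 g_bounds = g_bounds, smooth_fascicle = smooth_fascicle,
                 refine_peaks = refine_peaks, peak_twicing = peak_twicing,
                 fastest_speed = fastest_speed,
                 slowest_speed = slowest_speed, iso_hold_s = iso_hold_s),
            class = "pipeline_config")
}

# condition + correct one active trial against the filtered passive trace
condition_trial <- function(trial, passive_f, config, twicing = 0) {
  f <- filter_torque(trial$torque, config$filter_cutoff, config$filter_order,
                     twicing = twicing)
  correct_passive(f, passive_f)
}

# isometric plateau readings, taken over the hold phase at the end of the
# ramp-and-hold protocol (the last `hold_s` seconds of the trial). The
# plateau torque is the mean over that span -- unbiased for a flat
# plateau, unlike the pointwise maximum of a noisy signal -- and the
# plateau fascicle length is the median of the raw frames inside it
plateau_reading <- function(trial, corrected, hold_s = 2) {
  t_end <- max(corrected$time_s)
  hold <- corrected$time_s >= t_end - hold_s
  keep <- trial$fascicle$time_s >= t_end - hold_s
  if (!any(keep))
    af_stop("no fascicle frames during the torque plateau",
            "archforce_trial_error")
  c(torque = mean(corrected$torque_Nm[hold]),
    length = median(trial$fascicle$fascicle_length_mm[keep]))
}

process_participant <- function(participant, config) {
  trials <- participant$trials
  modes <- vapply(trials, function(tr) tr$mode, character(1))
  pas <- trials[[which(modes == "passive")[1]]]
  passive_f <- filter_torque(pas$torque, config$filter_cutoff,
                             config$filter_order)

  # force-length points from the isometric plateaus
  iso <- trials[modes == "isometric"]
  fl_pts <- do.call(rbind, lapply(iso, function(tr) {
    corr <- condition_trial(tr, passive_f, config)
    angle <- median(corr$angle_deg)
    rd <- plateau_reading(tr, corr, config$iso_hold_s)
    data.frame(angle = angle, L = unname(rd["length"]),
               F = knee_extension_force(unname(rd["torque"]), angle,
                                        config$moment_arm))
  }))
  fl <- fit_force_length(fl_pts$L, fl_pts$F, rho = config$rho)

  # per-speed peak force and fascicle velocity in the iso-velocity phase
  isok <- trials[modes == "isokinetic"]
  peak_rows <- list(); work_rows <- list()
  for (tr in isok) {
    corr <- condition_trial(tr, passive_f, config)
    win <- isovelocity_window(corr, config$window_angles)
    corr_pk <- if (config$peak_twicing > 0)
      condition_trial(tr, passive_f, config,
                      twicing = config$peak_twicing) else corr
    force <- data.frame(
      time_s = corr_pk$time_s,
      force_N = knee_extension_force(corr_pk$torque_Nm, corr_pk$angle_deg,
                                     config$moment_arm))
    pkF <- peak_in_window(force, win, refine = config$refine_peaks)
    fser <- tr$fascicle
    phase <- win$end_time - win$start_time
    dt_f <- median(diff(fser$time_s))
    if (config$smooth_fascicle) {
      vser <- data.frame(time_s = fser$time_s,
                         velocity_mm_s = sgolay_velocity(fser, phase))
      smoothed <- smooth_fascicle_series(fser, phase)
      # frame-noise estimate from the smoothing residuals (robust, so the
      # kink regions of the motion do not inflate it), propagated through
      # the local-slope design variance of the velocity estimator
      sig_L <- mad(fser$fascicle_length_mm - smoothed$fascicle_length_mm)
      n_sg <- sg_vel_span(dt_f, phase, nrow(fser))
      var_v <- sig_L^2 * 12 / (dt_f^2 * n_sg * (n_sg^2 - 1))
      fser <- smoothed
    } else {
      vser <- data.frame(time_s = fser$time_s,
                         velocity_mm_s = fascicle_velocity(fser))
      var_v <- 0
    }
    # torque-noise estimate from the high-frequency filter residuals,
    # scaled to the noise that survives the peak reading
    sig_tau <- mad(tr$torque$torque_Nm -
                     filter_torque(tr$torque, config$filter_cutoff,
                                   config$filter_order)$torque_Nm)
    arm_mid <- eval_moment_arm(config$moment_arm,
                               mean(config$window_angles))
    var_F <- (0.3 * sig_tau / arm_mid)^2
    # no sub-sample refinement for velocity: the iso-velocity phase has a
    # flat-topped profile on which a parabolic vertex is meaningless
    pkV <- peak_in_window(vser, win, refine = FALSE)
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      speed_deg_s = tr$nominal,
      peak_force_N = unname(pkF["force_N"]),
      peak_velocity_mm_s = unname(pkV["velocity_mm_s"]),
      var_force = var_F, var_velocity = var_v)

    # work: joint work on (angle, torque); muscle work on the torque time
    # base with fascicle state linearly interpolated onto it
    Lm_f <- muscle_length(fser$fascicle_length_mm, fser$pennation_deg)
    mser <- data.frame(
      time_s = corr$time_s,
      force_N = vastus_lateralis_force(pmax(0, force$force_N), config$share),
      muscle_length_mm = approx(fser$time_s, Lm_f, corr$time_s,
                                rule = 2)$y)
    work_rows[[length(work_rows) + 1L]] <- data.frame(
      participant_id = participant$id,
      speed_deg_s = tr$nominal,
      joint_work_J = joint_work(corr, win),
      muscle_work_J = muscle_work(mser, win))
  }
  peaks <- do.call(rbind, peak_rows)
  # two-stage fit: an ordinary fit supplies the curve slope with which the
  # velocity uncertainty is converted into force units, then each point is
  # weighted by its inverse effective variance. For noiseless data the
  # variance floor makes the weights uniform, and a weighted fit cannot
  # move an interpolating solution
  fv0 <- suppressWarnings(
    fit_force_velocity(peaks$peak_velocity_mm_s, peaks$peak_force_N,
                       force_max = fl$force_max, g_bounds = config$g_bounds))
  phi <- pmin(peaks$peak_velocity_mm_s / fv0$vmax, 1)
  dFdv <- fl$force_max * (1 + fv0$G) / (1 + fv0$G * phi)^2 / fv0$vmax
  var_eff <- peaks$var_force + dFdv^2 * peaks$var_velocity +
    (1e-6 * fl$force_max)^2
  fv <- suppressWarnings(
    fit_force_velocity(peaks$peak_velocity_mm_s, peaks$peak_force_N,
                       force_max = fl$force_max, g_bounds = config$g_bounds,
                       weights = 1 / var_eff))
  summ <- summarise_forces(fl, fv, peaks, share = config$share,
                           fastest_speed = config$fastest_speed,
                           slowest_speed = config$slowest_speed)
  summ <- cbind(data.frame(participant_id = participant$id), summ)

  # architecture from the stored scenes
  arch <- list(
    REST_0 = with(participant$scenes$REST_0, composite_fascicle_panoramic(
      superficial_fragments, deep_fragments, superficial_apo, deep_apo)),
    REST_60 = reconstruct_dual_probe(participant$scenes$REST_60, "REST_60"),
    MVC_60 = reconstruct_dual_probe(participant$scenes$MVC_60, "MVC_60"))

  list(id = participant$id, fl = fl, fv = fv, peaks = peaks,
       summary = summ, work = do.call(rbind, work_rows),
       architecture = arch)
}

arch_row <- function(arch) {
  out <- lapply(arch, function(a)
    setNames(c(a$fascicle_length, a$pennation, a$thickness),
             paste0(c("fascicle_length_", "pennation_", "thickness_"),
                    tolower(sub("_", "", a$condition)))))
  as.data.frame(as.list(unlist(unname(out))))
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, per participant: torque filtering and passive correction,
#' force-length fitting from the six isometric plateaus, iso-velocity
#' window location and peak force/velocity extraction for the five
#' isokinetic speeds, Hill force-velocity fitting with the force-length
#' maximum held fixed, joint and muscle work over the common iso-velocity
#' phase, and architecture reconstruction from the probe scenes. Then
#' assembles the cohort table, the Pearson correlation matrix between
#' architecture and force/work variables, normality screens and the
#' mean +/- SD summary. The pipeline is deterministic: re-running on the
#' same inputs reproduces identical results.
#'
#' @param cohort a `"muscle_cohort"` from [generate_cohort()], or a
#'   directory written by [write_cohort()].
#' @param config a [pipeline_config()].
#' @return an object of class `"pipeline_result"`: a list with `summaries`,
#'   `work`, `cohort_table`, `correlations`, `normality`, `cohort_stats`,
#'   `recovery` (estimates vs ground truth, when truth is available) and
#'   the per-participant `fits`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(cohort, "muscle_cohort"))
    af_stop("cohort must be a muscle_cohort or a cohort directory",
            "archforce_orchestration_error")
  results <- lapply(cohort$participants, function(p) {
    tryCatch(process_participant(p, config),
             archforce_error = function(e)
               af_stop(sprintf("participant %s: %s", p$id, conditionMessage(e)),
                       "archforce_orchestration_error"))
  })

  summaries <- do.call(rbind, lapply(results, function(r) r$summary))
  work <- do.call(rbind, lapply(results, function(r) r$work))
  arch_tab <- do.call(rbind, lapply(results, function(r)
    arch_row(r$architecture)))
  work_wide <- do.call(rbind, lapply(results, function(r) {
    w <- r$work
    as.data.frame(as.list(setNames(
      c(w$joint_work_J, w$muscle_work_J),
      c(paste0("joint_work_", w$speed_deg_s),
        paste0("muscle_work_", w$speed_deg_s)))))
  }))
  cohort_table <- cbind(summaries, arch_tab, work_wide)
  rownames(cohort_table) <- NULL

  arch_vars <- names(arch_tab)
  force_vars <- c("force_max", "force_iso400", "G", "force_slope_L0_s")
  pairs <- rbind(
    expand.grid(var_x = arch_vars, var_y = force_vars,
                stringsAsFactors = FALSE),
    expand.grid(var_x = grep("^fascicle_length", arch_vars, value = TRUE),
                var_y = names(work_wide), stringsAsFactors = FALSE))
  correlations <- if (nrow(cohort_table) >= 3L)
    pearson_matrix(cohort_table, pairs) else NULL

  normality <- if (nrow(cohort_table) >= 5L)
    lapply(setNames(force_vars, force_vars), function(v)
      normality_screen(cohort_table[[v]])) else NULL

  recovery <- NULL
  if (!is.null(cohort$participants[[1]]$truth$force_max_true)) {
    recovery <- do.call(rbind, lapply(seq_along(results), function(i) {
      tr <- cohort$participants[[i]]$truth
      est <- results[[i]]$summary
      data.frame(
        participant_id = tr$id,
        force_max_true = tr$force_max_true, force_max_est = est$force_max,
        L0_true = tr$L0_true, L0_est = est$L0,
        vmax_true_L0_s = tr$vmax_true_L0_s, vmax_est_L0_s = est$vmax_L0_s,
        G_true = tr$G_true, G_est = est$G)
    }))
    rownames(recovery) <- NULL
  }

  structure(list(config = config, summaries = summaries, work = work,
                 cohort_table = cohort_table, correlations = correlations,
                 normality = normality,
                 cohort_stats = if (nrow(cohort_table) >= 2L)
                   cohort_summary(
                     cohort_table[vapply(cohort_table, is.numeric,
                                         logical(1))]) else NULL,
                 recovery = recovery,
                 fits = results),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d participants\n", nrow(x$summaries)))
  cat(sprintf("  force_max %.0f +/- %.0f N | force_iso400 %.0f +/- %.0f N\n",
              mean(x$summaries$force_max), sd(x$summaries$force_max),
              mean(x$summaries$force_iso400), sd(x$summaries$force_iso400)))
  cat(sprintf("  L0 %.1f +/- %.1f mm | G %.2f +/- %.2f | vmax %.1f +/- %.1f L0/s\n",
              mean(x$summaries$L0), sd(x$summaries$L0),
              mean(x$summaries$G), sd(x$summaries$G),
              mean(x$summaries$vmax_L0_s), sd(x$summaries$vmax_L0_s)))
  invisible(x)
}

#' Parameter-recovery errors of a pipeline run
#'
#' Relative errors of the estimated contractile parameters against the
#' simulated ground truth (`|est - true| / true`), and the absolute
#' curvature error, per participant.
#'
#' @param result a [run_pipeline()] result on a synthetic cohort.
#' @return data frame of per-participant recovery errors.
#' @export
recovery_errors <- function(result) {
  r <- result$recovery
  if (is.null(r))
    af_stop("no ground truth available in this run", "archforce_input_error")
  data.frame(
    participant_id = r$participant_id,
    rel_err_force_max = abs(r$force_max_est - r$force_max_true) /
      r$force_max_true,
    rel_err_L0 = abs(r$L0_est - r$L0_true) / r$L0_true,
    rel_err_vmax = abs(r$vmax_est_L0_s - r$vmax_true_L0_s) /
      r$vmax_true_L0_s,
    rel_err_G = abs(r$G_est - r$G_true) / r$G_true,
    abs_err_G = abs(r$G_est - r$G_true))
}
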