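# File interchange: trial CSVs, segmentation CSVs, cohort directories with
# a JSON manifest, and codebook-mapped supplementary tables. CSV is the
# interchange format; all angles are stored in degrees and converted to
# radians only inside computations.

fmt_num <- function(x) sprintf("%.15g", x)

trial_schema <- c("time_s", "angle_deg", "torque_Nm")

#' Write a dynamometer trial to CSV
#'
#' Columns `time_s, angle_deg, torque_Nm`; numbers are written with 15
#' significant digits so a write/read round trip is numerically faithful.
#'
#' @param trace a [torque_trace()].
#' @param path output file.
#' @export
write_trial_csv <- function(trace, path) {
  df <- data.frame(time_s = fmt_num(trace$time_s),
                   angle_deg = fmt_num(trace$angle_deg),
                   torque_Nm = fmt_num(trace$torque_Nm))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dynamometer trial from CSV
#'
#' Expects the exact header `time_s, angle_deg, torque_Nm` (optionally
#' followed by `fascicle_length_mm, pennation_deg` for merged tables),
#' UTF-8, decimal point. Schema violations name the offending column;
#' non-monotone time is a data error.
#'
#' @param path input file.
#' @param mode,nominal trial attributes to attach (see [torque_trace()]).
#' @return a [torque_trace()]; any fascicle columns are kept as extra
#'   columns.
#' @export
read_trial_csv <- function(path, mode = "isometric", nominal = NA_real_) {
  if (!file.exists(path))
    af_stop(sprintf("no such file: %s", path), "archforce_schema_error")
  df <- read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(trial_schema, names(df))
  if (length(missing) > 0L)
    af_stop(sprintf("trial file %s lacks required column(s): %s",
                    basename(path), paste(missing, collapse = ", ")),
            "archforce_schema_error")
  tr <- torque_trace(df$time_s, df$angle_deg, df$torque_Nm,
                     mode = mode, nominal = nominal)
  extra <- setdiff(names(df), trial_schema)
  for (cn in extra) tr[[cn]] <- df[[cn]]
  tr
}

write_fascicle_csv <- function(fascicle, path) {
  df <- data.frame(time_s = fmt_num(fascicle$time_s),
                   fascicle_length_mm = fmt_num(fascicle$fascicle_length_mm),
                   pennation_deg = fmt_num(fascicle$pennation_deg))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_fascicle_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "fascicle_length_mm", "pennation_deg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    af_stop(sprintf("fascicle file %s lacks required column(s): %s",
                    basename(path), paste(missing, collapse = ", ")),
            "archforce_schema_error")
  df
}

#' Write dual-probe segmentation coordinates to CSV
#'
#' Long format: `frame_id, probe_id, feature, point_index, x_mm, y_mm`,
#' coordinates in each probe's local image frame.
#'
#' @param scene a scene from [generate_probe_scene()].
#' @param path output file.
#' @param frame_id frame number to record.
#' @export
write_segmentation_csv <- function(scene, path, frame_id = 1L) {
  rows <- list()
  for (pid in names(scene$segments)) {
    for (feat in names(scene$segments[[pid]])) {
      p <- scene$segments[[pid]][[feat]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame_id = frame_id, probe_id = pid, feature = feat,
        point_index = seq_len(nrow(p)),
        x_mm = fmt_num(p[, 1]), y_mm = fmt_num(p[, 2]))
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dual-probe segmentation coordinates from CSV
#'
#' @param path file written by [write_segmentation_csv()].
#' @param frames named list of [probe_frame()]s for the probes appearing in
#'   the file.
#' @return a scene list (`segments`, `frames`) usable by
#'   [reconstruct_dual_probe()].
#' @export
read_segmentation_csv <- function(path, frames) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("frame_id", "probe_id", "feature", "point_index", "x_mm", "y_mm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    af_stop(sprintf("segmentation file lacks column(s): %s",
                    paste(missing, collapse = ", ")),
            "archforce_schema_error")
  segments <- lapply(split(df, df$probe_id), function(dp)
    lapply(split(dp, dp$feature), function(dfF) {
      dfF <- dfF[order(dfF$point_index), ]
      cbind(dfF$x_mm, dfF$y_mm)
    }))
  list(segments = segments, frames = frames)
}

frame_to_list <- function(fr) {
  list(probe_id = fr$probe_id, origin = fr$origin,
       rotation_deg = fr$rotation_deg, field_width = fr$field_width,
       field_depth = fr$field_depth)
}

list_to_frame <- function(l) {
  probe_frame(l$probe_id, unlist(l$origin), l$rotation_deg,
              l$field_width, l$field_depth)
}

arch_to_list <- function(a) a[c("condition", "fascicle_length",
                                "pennation", "thickness")]

list_to_arch <- function(l)
  architecture_measure(l$condition, l$fascicle_length, l$pennation,
                       l$thickness)

#' Write a synthetic cohort to a directory
#'
#' One sub-directory per participant with one CSV per dynamometer trial
#' (`time_s, angle_deg, torque_Nm`), matching fascicle series CSVs,
#' segmentation CSVs for the dual-probe conditions, and a cohort manifest
#' (`cohort.json`) holding the configuration, seeds, ground truth,
#' panoramic scenes and probe frames. The manifest plus the CSVs fully
#' reproduce the in-memory cohort.
#'
#' @param cohort a `"muscle_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  manifest <- list(
    package = "archforce",
    config = list(
      n_participants = cfg$n_participants, seed = cfg$seed,
      sampling_rate = cfg$sampling_rate, fascicle_rate = cfg$fascicle_rate,
      noise_torque_sd = cfg$noise_torque_sd,
      noise_length_sd = cfg$noise_length_sd,
      noise_pennation_sd = cfg$noise_pennation_sd,
      isometric_angles = cfg$isometric_angles,
      isokinetic_speeds = cfg$isokinetic_speeds,
      pcsa_share = cfg$pcsa_share,
      length_angle_slope = cfg$length_angle_slope,
      optimal_angle = cfg$optimal_angle,
      moment_arm = list(coefficients = cfg$moment_arm$coefficients,
                        angle_range = cfg$moment_arm$angle_range),
      passive = cfg$passive),
    participants = lapply(cohort$participants, function(p) {
      pdir <- file.path(dir, p$id)
      dir.create(pdir, showWarnings = FALSE)
      trial_index <- lapply(names(p$trials), function(nm) {
        tr <- p$trials[[nm]]
        tfile <- paste0(nm, ".csv")
        write_trial_csv(tr$torque, file.path(pdir, tfile))
        ffile <- NULL
        if (!is.null(tr$fascicle)) {
          ffile <- paste0(nm, "_fascicle.csv")
          write_fascicle_csv(tr$fascicle, file.path(pdir, ffile))
        }
        list(name = nm, mode = tr$mode, nominal = tr$nominal,
             torque_file = tfile, fascicle_file = ffile)
      })
      for (cond in c("REST_60", "MVC_60"))
        write_segmentation_csv(p$scenes[[cond]],
                               file.path(pdir, paste0("seg_", cond, ".csv")))
      pan <- p$scenes$REST_0
      truth <- p$truth
      truth$rest0_arch <- arch_to_list(truth$rest0_arch)
      truth$rest60_arch <- arch_to_list(truth$rest60_arch)
      truth$mvc60_arch <- arch_to_list(truth$mvc60_arch)
      list(id = p$id, truth = truth, trials = trial_index,
           panoramic = list(deep_fragments = pan$deep_fragments,
                            superficial_fragments = pan$superficial_fragments,
                            deep_apo = pan$deep_apo,
                            superficial_apo = pan$superficial_apo),
           frames = lapply(p$scenes$REST_60$frames, frame_to_list))
    }))
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' @param dir a directory written by [write_cohort()].
#' @return a `"muscle_cohort"`.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "cohort.json")
  if (!dir.exists(dir) || !file.exists(mf_path))
    af_stop(sprintf("'%s' is not a cohort directory (no cohort.json)", dir),
            "archforce_orchestration_error")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  cfgl <- mf$config
  config <- simulation_config(
    n_participants = cfgl$n_participants, seed = cfgl$seed,
    sampling_rate = cfgl$sampling_rate, fascicle_rate = cfgl$fascicle_rate,
    noise_torque_sd = cfgl$noise_torque_sd,
    noise_length_sd = cfgl$noise_length_sd,
    noise_pennation_sd = cfgl$noise_pennation_sd,
    isometric_angles = cfgl$isometric_angles,
    isokinetic_speeds = cfgl$isokinetic_speeds,
    pcsa_share = cfgl$pcsa_share,
    length_angle_slope = cfgl$length_angle_slope,
    optimal_angle = cfgl$optimal_angle,
    moment_arm = moment_arm_model(unlist(cfgl$moment_arm$coefficients),
                                  unlist(cfgl$moment_arm$angle_range)),
    passive = cfgl$passive)
  participants <- lapply(mf$participants, function(pm) {
    pdir <- file.path(dir, pm$id)
    truth <- pm$truth
    truth$rest0_arch <- list_to_arch(truth$rest0_arch)
    truth$rest60_arch <- list_to_arch(truth$rest60_arch)
    truth$mvc60_arch <- list_to_arch(truth$mvc60_arch)
    trials <- lapply(pm$trials, function(ti) {
      tq <- read_trial_csv(file.path(pdir, ti$torque_file),
                           mode = ti$mode,
                           nominal = ti$nominal %||% NA_real_)
      fas <- NULL
      if (length(ti$fascicle_file) == 1L && nzchar(ti$fascicle_file))
        fas <- read_fascicle_csv(file.path(pdir, ti$fascicle_file))
      list(participant_id = pm$id, mode = ti$mode,
           nominal = ti$nominal %||% NA_real_, torque = tq, fascicle = fas)
    })
    names(trials) <- vapply(pm$trials, function(ti) ti$name, character(1))
    frames <- lapply(pm$frames, list_to_frame)
    scenes <- list(
      REST_0 = c(pm$panoramic, list(truth = truth$rest0_arch)),
      REST_60 = c(read_segmentation_csv(
        file.path(pdir, "seg_REST_60.csv"), frames),
        list(truth = truth$rest60_arch)),
      MVC_60 = c(read_segmentation_csv(
        file.path(pdir, "seg_MVC_60.csv"), frames),
        list(truth = truth$mvc60_arch)))
    list(id = pm$id, truth = truth, trials = trials, scenes = scenes)
  })
  structure(list(participants = participants, config = config),
            class = "muscle_cohort")
}

#' Load a per-participant supplementary table through a codebook
#'
#' Reads a delimited per-participant table of architecture and force/work
#' variables and maps its columns onto the pipeline's standard variable
#' names through a codebook (a named vector: standard name -> column name
#' in the file). Unmapped file columns are preserved with a warning, so no
#' information is dropped silently.
#'
#' @param path CSV file, one row per participant.
#' @param codebook named character vector or list mapping standard variable
#'   names (e.g. `participant_id`, `fascicle_length_rest0`, `force_max`)
#'   to the file's column names. Must map `participant_id`.
#' @return a data frame with standard variable names (plus preserved
#'   unmapped columns).
#' @export
read_supplementary_table <- function(path, codebook) {
  if (!file.exists(path))
    af_stop(sprintf("no such file: %s", path), "archforce_schema_error")
  codebook <- unlist(codebook)
  if (!"participant_id" %in% names(codebook))
    af_stop("codebook must map 'participant_id'", "archforce_mapping_error")
  df <- read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
  missing <- codebook[!codebook %in% names(df)]
  if (length(missing) > 0L)
    af_stop(sprintf(
      "codebook column(s) not found in table: %s; available columns: %s",
      paste(missing, collapse = ", "), paste(names(df), collapse = ", ")),
      "archforce_mapping_error")
  out <- df[, unname(codebook), drop = FALSE]
  names(out) <- names(codebook)
  unmapped <- setdiff(names(df), unname(codebook))
  if (length(unmapped) > 0L) {
    warning(sprintf("unmapped column(s) preserved: %s",
                    paste(unmapped, collapse = ", ")), call. = FALSE)
    out <- cbind(out, df[, unmapped, drop = FALSE])
  }
  out
}
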