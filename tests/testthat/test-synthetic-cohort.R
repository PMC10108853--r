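test_that("identical configs and seeds give identical cohorts", {
  cfg <- simulation_config(n_participants = 2, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants[[1]]$truth, b$participants[[1]]$truth)
  expect_identical(a$participants[[2]]$trials$isok_400$torque$torque_Nm,
                   b$participants[[2]]$trials$isok_400$torque$torque_Nm)
  expect_identical(a$participants[[1]]$trials$iso_60$fascicle,
                   b$participants[[1]]$trials$iso_60$fascicle)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(n_participants = 1),
               class = "archforce_config_error")
  expect_error(simulation_config(noise_torque_sd = -1),
               class = "archforce_config_error")
  expect_error(simulation_config(sampling_rate = 0),
               class = "archforce_config_error")
  expect_error(simulation_config(pcsa_share = 1.5),
               class = "archforce_config_error")
})

test_that("each participant carries the full study protocol", {
  cfg <- noiseless_config(n = 2, seed = 4)
  co <- generate_cohort(cfg)
  expect_length(co$participants, 2)
  p <- co$participants[[1]]
  modes <- vapply(p$trials, function(tr) tr$mode, character(1))
  expect_equal(sum(modes == "isometric"), 6)
  expect_equal(sum(modes == "isokinetic"), 5)
  expect_equal(sum(modes == "passive"), 1)
  # isokinetic trials span the full range of motion 110 -> 0
  ik <- p$trials$isok_200$torque
  expect_equal(max(ik$angle_deg), 110)
  expect_equal(min(ik$angle_deg), 0)
  expect_true(all(diff(ik$time_s) > 0))
  expect_true(all(p$trials$iso_80$fascicle$fascicle_length_mm > 0))
  # ground truth respects its declared invariants
  tr <- p$truth
  expect_gt(tr$force_max_true, 0)
  expect_gt(tr$vmax_true_L0_s, 0)
  expect_true(tr$G_true > 3 && tr$G_true < 9)
})

test_that("default distributions reproduce the cohort-level curvature mean", {
  co <- generate_cohort(simulation_config(n_participants = 21, seed = 12))
  g <- vapply(co$participants, function(p) p$truth$G_true, numeric(1))
  se <- 2.7 / sqrt(21)
  expect_lt(abs(mean(g) - 6.1), 2 * se)
})

test_that("probe scenes reconstruct their generating architecture exactly", {
  arch <- architecture_measure("MVC_60", fascicle_length = 40,
                               pennation = 30, thickness = 20)
  rec <- reconstruct_dual_probe(generate_probe_scene(arch))
  expect_equal(rec$fascicle_length, 40, tolerance = 1e-9)
  expect_equal(rec$pennation, 30, tolerance = 1e-9)
  expect_equal(rec$thickness, 20, tolerance = 1e-9)

  # identity frames leave local coordinates equal to world coordinates
  frames_id <- list(distal = probe_frame("distal"),
                    proximal = probe_frame("proximal"))
  sc <- generate_probe_scene(arch, frames = frames_id)
  expect_equal(sc$segments$distal$deep_apo[, 2], rep(0, 8))
  expect_equal(sc$segments$distal$superficial_apo[, 2], rep(20, 8))

  expect_error(generate_probe_scene(
    architecture_measure("MVC_60", 40, 30, 20), fascicle_x0 = 500),
    class = "archforce_geometry_error")
})

test_that("reconstruction is invariant to rigid probe placement", {
  set.seed(55)
  arch <- architecture_measure("REST_60", fascicle_length = 110,
                               pennation = 11, thickness = 110 * sin(11 * pi / 180))
  base <- reconstruct_dual_probe(generate_probe_scene(arch))
  for (i in 1:100) {
    frames <- list(
      distal = probe_frame("distal", origin = runif(2, -50, 50),
                           rotation_deg = runif(1, -180, 180)),
      proximal = probe_frame("proximal", origin = runif(2, -50, 50),
                             rotation_deg = runif(1, -180, 180)))
    rec <- reconstruct_dual_probe(generate_probe_scene(arch, frames = frames))
    expect_lt(abs(rec$fascicle_length - base$fascicle_length), 1e-9)
    expect_lt(abs(rec$pennation - base$pennation), 1e-9)
  }
})

test_that("estimator error of G and vmax shrinks along a noise ladder", {
  cfg_for <- function(tq, ln) simulation_config(
    n_participants = 2, seed = 1, noise_torque_sd = tq,
    noise_length_sd = ln, noise_pennation_sd = ln / 2)
  levels <- list(c(4, 2), c(1, 0.5), c(0, 0))
  med_err <- vapply(seq_along(levels), function(li) {
    cfg <- cfg_for(levels[[li]][1], levels[[li]][2])
    truth <- representative_truth(cfg)
    errs <- vapply(1:4, function(r) {
      set.seed(4000 + r)
      p <- simulate_participant(cfg, truth = truth)
      res <- suppressWarnings(run_pipeline(muscle_cohort(list(p), cfg)))
      abs(res$summaries$G - truth$G_true) +
        abs(res$summaries$vmax_L0_s - truth$vmax_true_L0_s) /
          truth$vmax_true_L0_s
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})
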