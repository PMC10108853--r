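fl_ref <- list(force_max = 1000, L0 = 100, b = 2, s = 0.5)

test_that("force-length evaluation matches closed-form values", {
  expect_equal(eval_force_length(100, fl_ref), 1000)
  # L/L0 = 1.2, b = 2, s = 0.5: 1000 * exp(-0.88^2)
  expect_equal(eval_force_length(120, fl_ref), 1000 * exp(-0.88^2))
  expect_equal(eval_force_length(120, fl_ref), 461.0, tolerance = 1e-3)
  expect_error(eval_force_length(-1, fl_ref), class = "archforce_domain_error")
})

test_that("the force-length curve peaks exactly at L0 and decays to zero", {
  L <- seq(20, 300, by = 0.5)
  F <- eval_force_length(L, fl_ref)
  expect_equal(L[which.max(F)], 100)
  # numerical derivative changes sign only at the peak
  dF <- diff(F)
  expect_true(all(dF[L[-1] <= 100] > 0))
  expect_true(all(dF[L[-length(L)] >= 100] < 0))
  # limits: the short-length plateau is force_max * exp(-(1/s)^rho); the
  # long-length tail vanishes
  expect_equal(eval_force_length(1e-3, fl_ref),
               1000 * exp(-(1 / 0.5)^2), tolerance = 1e-6)
  expect_lt(eval_force_length(1e4, fl_ref), 1e-6)
})

test_that("force-length fitting recovers known parameters from 6 points", {
  cases <- list(
    c(force_max = 5295, L0 = 105, b = 1.5, s = 0.45),
    c(force_max = 3000, L0 = 90, b = 2.2, s = 0.30),
    c(force_max = 8000, L0 = 130, b = 0.9, s = 0.65))
  for (p in cases) {
    pl <- as.list(p)
    L <- pl$L0 * c(0.92, 0.97, 1.02, 1.1, 1.2, 1.3)
    F <- eval_force_length(L, pl)
    fit <- fit_force_length(L, F)
    expect_lt(max(abs(coef(fit) - p) / p), 1e-6)
    # the theoretical peak sits between samples, above every observed force
    expect_gte(fit$force_max, max(F))
  }
  expect_error(fit_force_length(c(90, 100, 110), c(1, 2, 1)),
               class = "archforce_input_error")
})

fv_ref <- list(force_max = 1000, vmax = 10, G = 6)

test_that("Hill force-velocity evaluation matches closed-form values", {
  expect_equal(eval_force_velocity(0, fv_ref), 1000)
  expect_equal(eval_force_velocity(10, fv_ref), 0)
  expect_equal(eval_force_velocity(5, fv_ref), 1000 * 0.5 / 4)  # 125 N
  expect_error(eval_force_velocity(11, fv_ref),
               class = "archforce_domain_error")
})

test_that("the Hill curve is strictly decreasing for any curvature", {
  v <- seq(0, 10, length.out = 1000)
  for (G in c(0.5, 3.01, 6, 8.99, 20)) {
    F <- eval_force_velocity(v, list(force_max = 1000, vmax = 10, G = G))
    expect_true(all(diff(F) < 0))
  }
})

test_that("force-velocity fitting recovers (vmax, G) across the band", {
  v <- 0.00795 * 105 * c(50, 100, 200, 300, 400)  # study-design velocities
  for (vmax in c(7, 17.5, 30, 44) * 105) {
    for (G in c(3.5, 6.1, 8.5)) {
      F <- 5295 * (1 - v / vmax) / (1 + G * v / vmax)
      fit <- fit_force_velocity(v, F, 5295)
      expect_lt(abs(fit$vmax - vmax) / vmax, 1e-4)
      expect_lt(abs(fit$G - G) / G, 1e-4)
      expect_false(fit$bound_hit)
    }
  }
  # the worked reference case: vmax = 10 L0/s, G = 5
  v2 <- c(0.5, 1, 2, 3, 4)
  F2 <- 1000 * (1 - v2 / 10) / (1 + 5 * v2 / 10)
  fit2 <- fit_force_velocity(v2, F2, 1000)
  expect_lt(abs(fit2$vmax - 10) / 10, 1e-4)
  expect_lt(abs(fit2$G - 5) / 5, 1e-4)
})

test_that("curvature solutions outside (3, 9) land on the bound and are flagged", {
  v <- c(0.5, 1, 2, 3, 4)
  F <- 1000 * (1 - v / 12) / (1 + 12 * v / 12)   # true G = 12
  expect_warning(fit <- fit_force_velocity(v, F, 1000),
                 "bound")
  expect_true(fit$bound_hit)
  expect_equal(fit$G, 9, tolerance = 1e-3)
})

test_that("degenerate force-velocity data are rejected", {
  expect_error(fit_force_velocity(c(1, 2, 3), c(1100, 1200, 1300), 1000),
               class = "archforce_fit_error")
  expect_error(fit_force_velocity(1, 500, 1000),
               class = "archforce_input_error")
})

test_that("force_slope matches the normalised Hill chord slope", {
  fv <- list(force_max = 1000, vmax = 100, G = 5)
  expect_equal(force_slope(fv, 10, 80), (0.04 - 0.60) / 70)
  expect_equal(force_slope(fv, 10, 80), -0.008)
  # in the linear limit (G -> 0) the slope is -1/vmax
  lin <- list(force_max = 1000, vmax = 50, G = 1e-9)
  expect_equal(force_slope(lin, 5, 45), -1 / 50, tolerance = 1e-6)
  expect_error(force_slope(fv, 10, 120), class = "archforce_domain_error")
  expect_error(force_slope(fv, 50, 50), class = "archforce_input_error")
})

test_that("the force summary assembles fits and measured peaks coherently", {
  pl <- list(force_max = 5000, L0 = 100, b = 1.5, s = 0.45)
  L <- 100 * c(0.92, 0.97, 1.02, 1.1, 1.2, 1.3)
  fl <- fit_force_length(L, eval_force_length(L, pl))
  vmax_mm <- 15 * 100
  v <- 0.00795 * 100 * c(50, 100, 200, 300, 400)
  Fv <- 5000 * (1 - v / vmax_mm) / (1 + 6 * v / vmax_mm)
  fv <- fit_force_velocity(v, Fv, fl$force_max)
  peaks <- data.frame(speed_deg_s = c(50, 100, 200, 300, 400),
                      peak_force_N = Fv, peak_velocity_mm_s = v)
  s <- summarise_forces(fl, fv, peaks)
  expect_lt(s$force_iso400, s$force_max)
  expect_equal(s$force_max, 5000, tolerance = 1e-6)
  expect_equal(s$G, 6, tolerance = 1e-4)
  expect_equal(s$vmax_L0_s, 15, tolerance = 1e-4)
  expect_lt(s$force_slope_L0_s, 0)
  expect_equal(s$force_slope_L0_s / s$force_slope_cm_s, 100 / 10)
  expect_equal(s$vl_force_max, 0.35 * 5000, tolerance = 1e-6)

  no400 <- peaks[peaks$speed_deg_s != 400, ]
  expect_error(summarise_forces(fl, fv, no400),
               class = "archforce_summary_error")
})
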