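test_that("zero-phase filter has unit DC gain and half-power at the cutoff", {
  tr <- const_trace(50)
  expect_lt(max(abs(filter_torque(tr)$torque_Nm - 50)), 1e-9)

  # well inside the passband the signal is untouched
  low <- filter_torque(sine_trace(2))
  expect_gt(interior_amplitude(low$torque_Nm), 0.99)

  # squared Butterworth magnitude at the cutoff: |H|^2 = 1/2
  at_cut <- filter_torque(sine_trace(20))
  expect_equal(interior_amplitude(at_cut$torque_Nm), 0.5, tolerance = 0.02)
})

test_that("the bidirectional filter is linear", {
  set.seed(42)
  t <- seq(0, 1, 1e-3)
  x <- cumsum(rnorm(length(t))); y <- cumsum(rnorm(length(t)))
  f <- function(v) filter_torque(make_trace(t, t * 0 + 60, v))$torque_Nm
  expect_lt(max(abs(f(3 * x - 2 * y) - (3 * f(x) - 2 * f(y)))), 1e-9)
})

test_that("twicing iterations reduce in-band attenuation monotonically", {
  amp <- function(k)
    interior_amplitude(filter_torque(sine_trace(10), twicing = k)$torque_Nm)
  a <- vapply(0:2, amp, numeric(1))
  expect_true(all(diff(abs(1 - a)) < 0))
  expect_equal(a[1], 1 / (1 + (10 / 20)^4), tolerance = 1e-3)
  # DC behaviour unchanged
  expect_lt(max(abs(filter_torque(const_trace(50), twicing = 2)$torque_Nm - 50)),
            1e-9)
})

test_that("filtering rejects unusable traces", {
  slow <- make_trace(seq(0, 1, 0.04), rep(60, 26), rnorm(26))
  expect_error(filter_torque(slow), class = "archforce_signal_error")
  short <- make_trace(seq(0, 0.005, 1e-3), rep(60, 6), rnorm(6))
  expect_error(filter_torque(short), class = "archforce_signal_error")
})

test_that("passive correction is angle-matched, not time-matched", {
  t <- seq(0, 2, 1e-3)
  ang <- 110 - 55 * t
  pas <- make_trace(t, ang, 0.3 * ang - 8, mode = "passive")

  # identical traces cancel exactly
  zero <- correct_passive(pas, pas)
  expect_lt(max(abs(zero$torque_Nm)), 1e-12)

  # an additive offset survives untouched
  act <- pas; act$torque_Nm <- act$torque_Nm + 10
  expect_equal(correct_passive(act, pas)$torque_Nm,
               rep(10, length(t)), tolerance = 1e-12)

  # coarse passive sampling of a quadratic passive curve: the active trial
  # runs on a different time base, so matching must happen through angle
  pfun <- function(a) 0.002 * a^2 - 0.1 * a + 3
  tp <- seq(0, 4, 0.05)
  pas2 <- make_trace(tp, 110 - 27.5 * tp, pfun(110 - 27.5 * tp),
                     mode = "passive")
  act2 <- make_trace(t, ang, pfun(ang) + 42)
  res <- correct_passive(act2, pas2)
  expect_lt(max(abs(res$torque_Nm - 42)), 1e-3)

  # coverage violation is an explicit error
  wide <- make_trace(t, 140 - 70 * t, rep(1, length(t)))
  expect_error(correct_passive(wide, pas),
               class = "archforce_extrapolation_error")
})

test_that("torque converts to force through the moment arm", {
  ma_const <- moment_arm_model(c(0.05), c(0, 110))
  expect_equal(knee_extension_force(150, 60, ma_const), 3000)
  expect_equal(knee_extension_force(0, 90, ma_const), 0)

  # polynomial model on a grid, against an explicit scalar loop
  ma <- moment_arm_model()
  tq <- seq(5, 250, length.out = 40)
  ang <- seq(0, 110, length.out = 40)
  f_vec <- knee_extension_force(tq, ang, ma)
  f_loop <- vapply(seq_along(tq), function(i) {
    arm <- 0.035 + 3.5e-4 * ang[i] - 3.5e-6 * ang[i]^2
    tq[i] / arm
  }, numeric(1))
  expect_equal(f_vec, f_loop, tolerance = 1e-12)

  # round trip: torque built from force x moment arm returns the force
  fr <- 1234.5
  tq2 <- fr * eval_moment_arm(ma, ang)
  expect_equal(knee_extension_force(tq2, ang, ma), rep(fr, 40),
               tolerance = 1e-12)

  expect_error(knee_extension_force(10, 200, ma),
               class = "archforce_model_error")
})

test_that("single-muscle force is the PCSA share of knee extension force", {
  expect_equal(vastus_lateralis_force(1000, 0.35), 350)
  expect_equal(vastus_lateralis_force(0), 0)
  # the default share matches the ratio of cohort-mean muscle force to
  # cohort-mean knee extension force it was derived from
  expect_equal(muscle_share_model()$pcsa_share, 1856 / 5295,
               tolerance = 0.005)
  expect_error(muscle_share_model(1.2), class = "archforce_config_error")
  expect_error(vastus_lateralis_force(-5), class = "archforce_input_error")
})

test_that("best-attempt selection keeps the highest peak, first on ties", {
  t <- seq(0, 1, 0.01)
  tr_lo <- make_trace(t, rep(60, 101), 210 * sin(pi * t))
  tr_hi <- make_trace(t, rep(60, 101), 230 * sin(pi * t))
  expect_identical(select_best_attempt(list(tr_lo, tr_hi)), tr_hi)
  expect_identical(select_best_attempt(list(tr_hi)), tr_hi)
  tie <- select_best_attempt(list(tr_lo, tr_lo))
  expect_identical(tie, tr_lo)
  expect_error(select_best_attempt(list()), class = "archforce_input_error")
})
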