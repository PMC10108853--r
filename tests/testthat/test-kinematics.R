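test_that("central-difference velocity matches simple and analytic cases", {
  s <- data.frame(time_s = c(0, 0.1, 0.2),
                  fascicle_length_mm = c(100, 99, 98))
  expect_equal(fascicle_velocity(s), c(10, 10, 10))

  const <- data.frame(time_s = seq(0, 1, 0.01),
                      fascicle_length_mm = rep(90, 101))
  expect_true(all(fascicle_velocity(const) == 0))

  t <- seq(0, 1, 0.01)   # 100 Hz sampling of a 1 Hz oscillation
  s2 <- data.frame(time_s = t, fascicle_length_mm = 100 - 5 * sin(2 * pi * t))
  v <- fascicle_velocity(s2)
  v_true <- 5 * 2 * pi * cos(2 * pi * t)
  i <- 2:(length(t) - 1)
  expect_lt(max(abs(v[i] - v_true[i])) / max(abs(v_true)), 0.002)
})

test_that("velocity is antisymmetric under time reversal", {
  set.seed(9)
  t <- sort(runif(50, 0, 2))
  L <- 100 + cumsum(rnorm(50))
  s <- data.frame(time_s = t, fascicle_length_mm = L)
  rev_s <- data.frame(time_s = max(t) - rev(t), fascicle_length_mm = rev(L))
  v <- fascicle_velocity(s)
  v_rev <- fascicle_velocity(rev_s)
  i <- 2:49
  expect_lt(max(abs(v[i] + rev(v_rev)[i])), 1e-12)
})

test_that("velocity rejects degenerate series", {
  expect_error(fascicle_velocity(data.frame(time_s = c(0, 1),
                                            fascicle_length_mm = c(1, 2))),
               class = "archforce_signal_error")
  dup <- data.frame(time_s = c(0, 0.1, 0.1, 0.2),
                    fascicle_length_mm = c(1, 2, 3, 4))
  expect_error(fascicle_velocity(dup), class = "archforce_signal_error")
})

test_that("muscle length is the pennation-cosine projection", {
  expect_equal(muscle_length(100, 0), 100)
  expect_equal(muscle_length(120.4, 10.9), 120.4 * cos(10.9 * pi / 180))
  expect_equal(muscle_length(120.4, 10.9), 118.2, tolerance = 1e-3)
  expect_equal(muscle_length(96.7, 14.5), 93.6, tolerance = 1e-3)
  expect_error(muscle_length(100, 90), class = "archforce_domain_error")
  # projection never exceeds fascicle length, equality only at zero
  pen <- seq(0, 89, 1)
  expect_true(all(muscle_length(100, pen) <= 100))
  expect_true(all(muscle_length(100, pen[-1]) < 100))
})

test_that("iso-velocity window crossing times are interpolated linearly", {
  t <- seq(0, 1.2, 1e-3)
  tr <- make_trace(t, pmax(0, 110 - 100 * t), rep(1, length(t)),
                   mode = "isokinetic", nominal = 100)
  w <- isovelocity_window(tr)
  expect_equal(w$start_time, 0.30, tolerance = 1e-9)
  expect_equal(w$end_time, 0.60, tolerance = 1e-9)

  t2 <- seq(0, 2.5, 1e-3)
  tr50 <- make_trace(t2, pmax(0, 110 - 50 * t2), rep(1, length(t2)))
  w50 <- isovelocity_window(tr50)
  expect_equal(w50$end_time - w50$start_time, 30 / 50, tolerance = 1e-9)

  # a ripple crossing 80 deg twice: the first extension crossing is used
  ang <- 110 - 100 * t + 3 * sin(40 * pi * t) * (t > 0.25 & t < 0.4)
  trip <- make_trace(t, ang, rep(1, length(t)))
  wr <- isovelocity_window(trip)
  first <- min(which(ang[-length(ang)] > 80 & ang[-1] <= 80))
  expect_lt(wr$start_time, t[first + 1] + 1e-6)

  never <- make_trace(t, rep(90, length(t)), rep(1, length(t)))
  expect_error(isovelocity_window(never), class = "archforce_trial_error")
})

test_that("windowed peaks select per-column maxima", {
  t <- seq(0, 1, 1e-3)
  w <- list(start_time = 0.3, end_time = 0.6)
  rising <- data.frame(time_s = t, force_N = 1000 * t)
  expect_equal(unname(peak_in_window(rising, w)), 600)

  bump <- data.frame(time_s = t,
                     force_N = 1200 - 4000 * (t - 0.45)^2,
                     velocity_mm_s = 50 + 10 * t)
  pk <- peak_in_window(bump, w)
  expect_equal(unname(pk["force_N"]), 1200, tolerance = 1e-4)
  expect_equal(unname(pk["velocity_mm_s"]), 56)

  # same sample as a brute-force scan over the discrete series
  set.seed(5)
  wig <- data.frame(time_s = t, force_N = cumsum(rnorm(length(t))))
  keep <- which(t >= 0.3 & t <= 0.6)
  expect_equal(unname(peak_in_window(wig, w)), max(wig$force_N[keep]))

  expect_error(peak_in_window(rising, list(start_time = 2, end_time = 3)),
               class = "archforce_trial_error")
})

test_that("parabolic refinement recovers an off-grid vertex", {
  t <- seq(0, 1, 0.01)
  w <- list(start_time = 0.2, end_time = 0.8)
  s <- data.frame(time_s = t, y = 100 - 500 * (t - 0.5037)^2)
  plain <- peak_in_window(s, w, refine = FALSE)
  refined <- peak_in_window(s, w, refine = TRUE)
  expect_lt(abs(refined - 100), abs(plain - 100))
  expect_lt(abs(refined - 100), 1e-9)
})
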