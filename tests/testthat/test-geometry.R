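test_that("probe fusion preserves coordinates under identity and translation", {
  pts <- cbind(c(0, 10, 20), c(0, 5, 10))
  frames <- list(distal = probe_frame("distal"),
                 proximal = probe_frame("proximal", origin = c(0, 60)))
  fused <- fuse_probe_frames(list(distal = list(f = pts),
                                  proximal = list(f = pts)), frames)
  expect_equal(fused$distal$f, pts)
  expect_equal(fused$proximal$f, sweep(pts, 2, c(0, 60), "+"))
})

test_that("rotation + translation fusion round-trips through its inverse", {
  pts <- cbind(runif(6, 0, 50), runif(6, 0, 30))
  fr <- probe_frame("proximal", origin = c(80, -3), rotation_deg = 5)
  local <- archforce:::probe_world_to_local(fr, pts)
  back <- archforce:::probe_local_to_world(fr, local)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("fascicle extrapolation matches right-triangle closed forms", {
  deep <- cbind(c(-10, 50), c(0, 0))
  sup <- cbind(c(-10, 50), c(20, 20))
  fas30 <- cbind(c(0, 10), c(0, 10 * tan(pi / 6)))
  r <- extrapolate_fascicle_length(fas30, sup, deep)
  expect_equal(r$fascicle_length, 40, tolerance = 1e-9)
  expect_equal(r$pennation, 30, tolerance = 1e-9)

  # perpendicular fascicle: length equals thickness
  fas90 <- cbind(c(5, 5, 5), c(0, 4, 8))
  r90 <- extrapolate_fascicle_length(fas90, sup, deep)
  expect_equal(r90$fascicle_length, 20, tolerance = 1e-9)

  # parallel fascicle has no intersection
  fas0 <- cbind(c(0, 10), c(5, 5))
  expect_error(extrapolate_fascicle_length(fas0, sup, deep),
               class = "archforce_no_intersection_error")
})

test_that("extrapolation agrees with a dense-sweep oracle on random scenes", {
  set.seed(101)
  for (i in 1:200) {
    sc <- random_scene()
    got <- extrapolate_fascicle_length(sc$fascicle, sc$superficial,
                                       sc$deep)$fascicle_length
    want <- oracle_extrapolation_length(sc$fascicle, sc$superficial, sc$deep)
    expect_lt(abs(got - want), 1e-6)
  }
})

test_that("all reconstruction outputs are rigid-motion invariant", {
  set.seed(202)
  for (i in 1:100) {
    sc <- random_scene()
    base <- extrapolate_fascicle_length(sc$fascicle, sc$superficial, sc$deep)
    th_base <- muscle_thickness(sc$superficial, sc$deep, roi = c(-10, 10))
    sc2 <- apply_rigid_scene(sc, random_rigid())
    moved <- extrapolate_fascicle_length(sc2$fascicle, sc2$superficial,
                                         sc2$deep)
    expect_lt(abs(moved$fascicle_length - base$fascicle_length), 1e-9)
    expect_lt(abs(moved$pennation - base$pennation), 1e-9)
    expect_lt(abs(muscle_thickness(sc2$superficial, sc2$deep,
                                   roi = c(-10, 10)) - th_base), 1e-9)
  }
})

test_that("shortest-candidate rule returns the minimum valid length", {
  expect_equal(shortest_candidate_length(c(85, 92)), 85)
  expect_equal(shortest_candidate_length(77), 77)
  expect_equal(shortest_candidate_length(c(90, 90)), 90)
  expect_equal(shortest_candidate_length(c(NA, Inf, 88, -3)), 88)
  expect_error(shortest_candidate_length(c(NA_real_, -1)),
               class = "archforce_reconstruction_error")
  # never above any valid candidate
  set.seed(3)
  for (i in 1:50) {
    cand <- runif(sample(1:6, 1), 40, 140)
    expect_true(shortest_candidate_length(cand) <= min(cand))
  }
})

test_that("muscle thickness is the mean inter-aponeurosis gap", {
  xs <- seq(-20, 20, 5)
  deep <- cbind(xs, 0)
  expect_equal(muscle_thickness(cbind(xs, 21.2), deep), 21.2,
               tolerance = 1e-9)
  # linear wedge from 20 to 24 mm across the ROI averages to 22
  wedge <- cbind(xs, 22 + 0.1 * xs)
  expect_equal(muscle_thickness(wedge, deep, roi = c(-20, 20)), 22,
               tolerance = 1e-9)
  expect_error(muscle_thickness(wedge, deep, roi = c(5, 5)),
               class = "archforce_input_error")
  crossing <- cbind(xs, xs)  # crosses the deep line inside the ROI
  expect_error(muscle_thickness(crossing, deep, roi = c(-20, 20)),
               class = "archforce_geometry_error")
})

test_that("panoramic composite reduces to the straight-fascicle closed form", {
  xs <- seq(0, 80, 10)
  deep <- cbind(xs, 0); sup <- cbind(xs, 21)
  m <- composite_fascicle_panoramic(15, 15, sup, deep)
  expect_equal(m$fascicle_length, 21 / sin(pi / 12), tolerance = 1e-6)
  expect_equal(m$pennation, 15)
  expect_equal(m$thickness, 21, tolerance = 1e-9)
})

test_that("curved composites are bracketed by the straight candidates", {
  xs <- seq(0, 80, 10)
  deep <- cbind(xs, 0); sup <- cbind(xs, 20)
  m <- composite_fascicle_panoramic(superficial_fragments = 10,
                                    deep_fragments = 20, sup, deep)
  lo <- 20 / sin(20 * pi / 180)
  hi <- 20 / sin(10 * pi / 180)
  expect_gt(m$fascicle_length, lo)
  expect_lt(m$fascicle_length, hi)
  # pennation reported against the deep aponeurosis = deep orientation
  expect_equal(m$pennation, 20)
})

test_that("panoramic and dual-probe reconstructions agree for straight fascicles", {
  set.seed(77)
  for (i in 1:20) {
    th <- runif(1, 15, 30); pen <- runif(1, 10, 40)
    xs <- seq(-10, 100, 10)
    deep <- cbind(xs, 0); sup <- cbind(xs, th)
    pano <- composite_fascicle_panoramic(pen, pen, sup, deep)
    tt <- seq(0, 8, 2)
    fas <- cbind(5 + tt * cos(pen * pi / 180), tt * sin(pen * pi / 180))
    lin <- extrapolate_fascicle_length(fas, sup, deep)
    expect_lt(abs(pano$fascicle_length - lin$fascicle_length), 1e-6)
  }
})

test_that("inconsistent fragment orientations are rejected", {
  xs <- seq(0, 80, 10)
  deep <- cbind(xs, 0); sup <- cbind(xs, 20)
  expect_error(composite_fascicle_panoramic(-5, 15, sup, deep),
               class = "archforce_reconstruction_error")
  expect_error(composite_fascicle_panoramic(95, 15, sup, deep),
               class = "archforce_reconstruction_error")
})
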