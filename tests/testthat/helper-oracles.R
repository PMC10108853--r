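# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (dense sweeps, explicit sums) and never
# reuse the implementation under test.

make_trace <- function(time, angle, torque, mode = "isometric",
                       nominal = NA_real_) {
  torque_trace(time, angle, torque, mode = mode, nominal = nominal)
}

const_trace <- function(value = 50, fs = 1000, dur = 1, angle = 60) {
  t <- seq(0, dur, by = 1 / fs)
  make_trace(t, rep(angle, length(t)), rep(value, length(t)))
}

sine_trace <- function(freq, fs = 1000, dur = 2, angle = 60) {
  t <- seq(0, dur, by = 1 / fs)
  make_trace(t, rep(angle, length(t)), sin(2 * pi * freq * t))
}

# amplitude of an oscillation, away from the trace edges
interior_amplitude <- function(x, frac = 0.25) {
  n <- length(x)
  i <- seq(floor(n * frac), ceiling(n * (1 - frac)))
  max(abs(x[i]))
}

noiseless_config <- function(n = 2, seed = 1, ...) {
  simulation_config(n_participants = n, seed = seed, noise_torque_sd = 0,
                    noise_length_sd = 0, noise_pennation_sd = 0, ...)
}

# brute-force oracle for fascicle extrapolation: sweep a dense parameter
# grid along the fascicle line, find where it meets each aponeurosis line
# (minimum point-line distance), and measure the span between the two
# crossings
oracle_extrapolation_length <- function(fascicle, superficial, deep) {
  fit <- function(p) {
    p <- as.matrix(p)
    ctr <- colMeans(p)
    d <- svd(sweep(p, 2, ctr))$v[, 1]
    list(ctr = ctr, dir = d / sqrt(sum(d^2)))
  }
  lf <- fit(fascicle); ls <- fit(superficial); ld <- fit(deep)
  dist_to <- function(pt, ln) {
    v <- pt - ln$ctr
    abs(v[1] * ln$dir[2] - v[2] * ln$dir[1])
  }
  crossing <- function(ln_target) {
    tt <- seq(-500, 500, length.out = 200001)
    d <- vapply(tt, function(s)
      dist_to(lf$ctr + s * lf$dir, ln_target), numeric(1))
    i <- which.min(d)
    # local linear refinement of the signed distance zero
    s0 <- tt[max(1, i - 1)]; s1 <- tt[min(length(tt), i + 1)]
    f <- function(s) {
      v <- lf$ctr + s * lf$dir - ln_target$ctr
      v[1] * ln_target$dir[2] - v[2] * ln_target$dir[1]
    }
    uniroot(f, c(s0 - 0.01, s1 + 0.01), extendInt = "yes",
            tol = 1e-12)$root
  }
  abs(crossing(ls) - crossing(ld))
}

# a random non-degenerate planar scene: two non-crossing aponeuroses and a
# fascicle segment rising from the deep one
random_scene <- function() {
  th <- runif(1, 10, 35)               # thickness, mm
  pen <- runif(1, 8, 60)               # pennation, deg
  tilt <- runif(1, -8, 8)              # superficial apo tilt, deg
  xs <- seq(-20, 80, length.out = 7)
  deep <- cbind(xs, 0)
  sup <- cbind(xs, th + tan(tilt * pi / 180) * xs)
  x0 <- runif(1, -5, 20)
  len_seg <- runif(1, 4, 12)
  tt <- seq(0, len_seg, length.out = 5)
  fas <- cbind(x0 + tt * cos(pen * pi / 180), tt * sin(pen * pi / 180))
  list(fascicle = fas, superficial = sup, deep = deep)
}

random_rigid <- function() {
  list(rot = runif(1, -180, 180), tr = runif(2, -100, 100))
}

apply_rigid_scene <- function(scene, rg) {
  lapply(scene, rigid_transform, rotation_deg = rg$rot, translation = rg$tr)
}

# Pearson correlation by explicit sums (textbook formula)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# path to the synthetic supplementary-table stand-in shipped with the
# package
synthetic_table_path <- function() {
  system.file("extdata", "synthetic_cohort_table.csv", package = "archforce")
}

synthetic_codebook <- function() {
  jsonlite::read_json(
    system.file("extdata", "synthetic_codebook.json", package = "archforce"),
    simplifyVector = TRUE)
}
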