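# Planar fascicle geometry: rigid probe fusion, line fitting,
# extrapolation to the superficial aponeurosis, panoramic composites.
#
# Coordinate convention: x along the muscle line of action (proximal
# positive), y = depth (superficial positive). All geometry is 2D, matching
# B-mode scans. Points are n x 2 matrices in mm.

as_points <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 2L || any(!is.finite(p)))
    af_stop("a point set must be a finite n x 2 matrix with n >= 2",
            "archforce_input_error")
  unname(p)
}

#' Apply a rigid 2D transform to points
#'
#' @param points an n x 2 matrix (mm).
#' @param rotation_deg counter-clockwise rotation in degrees.
#' @param translation length-2 translation vector (mm), applied after the
#'   rotation.
#' @return the transformed n x 2 matrix.
#' @export
rigid_transform <- function(points, rotation_deg = 0, translation = c(0, 0)) {
  p <- as_points(points)
  th <- deg2rad(rotation_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(p %*% t(R), 2, translation, "+")
}

#' Probe frame: rigid placement of one ultrasound transducer
#'
#' Describes where one transducer's image sits in the muscle frame: the
#' world position of the image origin, the in-plane rotation (which carries
#' the angulation between the two transducers of the dual-probe
#' holder), and the field of view. Local image coordinates map to world
#' coordinates by `world = R(rotation) %*% local + origin`; only rigid
#' motions are representable, so fused lengths and angles are preserved by
#' construction.
#'
#' @param probe_id `"proximal"` or `"distal"`.
#' @param origin world position (mm) of the image origin.
#' @param rotation_deg in-plane rotation of the image, degrees.
#' @param field_width,field_depth image extent (mm).
#' @return An object of class `"probe_frame"`.
#' @export
probe_frame <- function(probe_id = c("distal", "proximal"),
                        origin = c(0, 0), rotation_deg = 0,
                        field_width = 60, field_depth = 40) {
  probe_id <- match.arg(probe_id)
  if (length(origin) != 2L || any(!is.finite(origin)) ||
      !is.finite(rotation_deg))
    af_stop("probe frame must have a finite origin and rotation (rigid)",
            "archforce_geometry_error")
  if (field_width <= 0 || field_depth <= 0)
    af_stop("probe field of view must be positive", "archforce_geometry_error")
  structure(list(probe_id = probe_id, origin = as.numeric(origin),
                 rotation_deg = rotation_deg,
                 field_width = field_width, field_depth = field_depth),
            class = "probe_frame")
}

probe_local_to_world <- function(frame, points) {
  rigid_transform(points, frame$rotation_deg, frame$origin)
}

probe_world_to_local <- function(frame, points) {
  p <- sweep(as_points(points), 2, frame$origin, "-")
  rigid_transform(p, -frame$rotation_deg, c(0, 0))
}

#' Fuse dual-probe segmentations into a common coordinate system
#'
#' Takes feature point sets segmented in each probe's local image frame and
#' expresses them all in the reference frame (the distal probe's image
#' frame), using the rigid transforms encoded by the two [probe_frame()]s.
#' Lengths and angles between features are preserved.
#'
#' @param segments a named list with one entry per probe (`"distal"`,
#'   `"proximal"`), each a named list of n x 2 point matrices in that
#'   probe's local frame (features such as `fascicle`, `superficial_apo`,
#'   `deep_apo`).
#' @param frames a named list of the two [probe_frame()]s.
#' @return a list with the same feature structure, all coordinates in the
#'   distal-probe frame.
#' @export
fuse_probe_frames <- function(segments, frames) {
  if (!all(names(segments) %in% names(frames)))
    af_stop("every segmented probe needs a probe frame",
            "archforce_geometry_error")
  ref <- frames$distal
  if (is.null(ref))
    af_stop("the distal probe frame is the reference and must be present",
            "archforce_geometry_error")
  lapply(setNames(names(segments), names(segments)), function(pid) {
    fr <- frames[[pid]]
    if (!inherits(fr, "probe_frame"))
      af_stop("non-rigid or invalid probe frame", "archforce_geometry_error")
    lapply(segments[[pid]], function(pts)
      probe_world_to_local(ref, probe_local_to_world(fr, pts)))
  })
}

# total-least-squares line through a point cloud: centroid + principal
# direction. Robust to which way round the points are given.
fit_line_tls <- function(points) {
  p <- as_points(points)
  ctr <- colMeans(p)
  cc <- crossprod(sweep(p, 2, ctr))
  if (sum(cc^2) < 1e-24)
    af_stop("degenerate point set: no line direction", "archforce_geometry_error")
  ev <- eigen(cc, symmetric = TRUE)
  d <- ev$vectors[, 1]
  list(point = ctr, dir = d / sqrt(sum(d^2)))
}

# intersection parameters of two lines p1 + t*d1 = p2 + u*d2
line_intersection <- function(l1, l2) {
  d1 <- l1$dir; d2 <- l2$dir
  cr <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(cr) < 1e-12)
    af_stop("lines are parallel: no intersection",
            "archforce_no_intersection_error")
  dp <- l2$point - l1$point
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / cr
  list(point = l1$point + t * d1, t = t)
}

# acute angle (deg) between two directions
angle_between <- function(d1, d2) {
  c1 <- abs(sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2)))
  rad2deg(acos(pmin(1, c1)))
}

#' Fascicle length and pennation by linear extrapolation
#'
#' Fits total-least-squares lines to the fascicle segment and to the two
#' aponeurosis segments, then measures the fascicle as the distance from
#' its deep insertion (intersection with the deep aponeurosis line) to the
#' intersection with the linearly extended superficial aponeurosis.
#' Pennation is the acute angle between the fascicle line and the deep
#' aponeurosis line.
#'
#' @param fascicle n x 2 point matrix of the segmented fascicle (mm).
#' @param superficial,deep n x 2 point matrices of the superficial and deep
#'   aponeurosis segments (mm), in the same frame as `fascicle`.
#' @return a list with `fascicle_length` (mm), `pennation` (deg) and the
#'   two insertion points `deep_point`, `superficial_point`.
#' @export
#' @examples
#' # horizontal aponeuroses 20 mm apart, fascicle at 30 deg: L = 20/sin(30) = 40
#' deep <- cbind(c(-10, 50), c(0, 0))
#' sup  <- cbind(c(-10, 50), c(20, 20))
#' fas  <- cbind(c(0, 10), c(0, 10 * tan(pi / 6)))
#' extrapolate_fascicle_length(fas, sup, deep)$fascicle_length
extrapolate_fascicle_length <- function(fascicle, superficial, deep) {
  lf <- fit_line_tls(fascicle)
  ls <- fit_line_tls(superficial)
  ld <- fit_line_tls(deep)
  pd <- line_intersection(lf, ld)$point
  ps <- line_intersection(lf, ls)$point
  span <- ps - pd
  len <- sqrt(sum(span^2))
  if (len < 1e-9)
    af_stop("aponeuroses intersect the fascicle at the same point",
            "archforce_geometry_error")
  # orientation: the path from deep to superficial insertion must point
  # towards the superficial side (frame-independent via the apo centroids)
  toward_sup <- ls$point - (ld$point +
    sum((ls$point - ld$point) * ld$dir) * ld$dir)
  if (sum(span * toward_sup) <= 0)
    af_stop("fascicle meets the superficial aponeurosis on the wrong side",
            "archforce_orientation_error")
  list(fascicle_length = len,
       pennation = angle_between(lf$dir, ld$dir),
       deep_point = pd, superficial_point = ps)
}

#' Shortest-candidate rule for fascicle length
#'
#' When a fascicle extrapolated out of one field of view does not span to
#' the other, the superficial insertion is taken from the extrapolated
#' superficial aponeurosis of either field of view, whichever yields the
#' shortest fascicle length.
#'
#' @param candidates numeric vector of candidate lengths (mm); non-finite
#'   or non-positive entries are treated as failed reconstructions.
#' @return the minimum valid candidate length (mm).
#' @export
shortest_candidate_length <- function(candidates) {
  ok <- candidates[is.finite(candidates) & candidates > 0]
  if (length(ok) == 0L)
    af_stop("no valid fascicle length candidate", "archforce_reconstruction_error")
  min(ok)
}

#' Mean muscle thickness between aponeuroses
#'
#' Thickness is the mean gap between the two aponeuroses over a region of
#' interest, measured perpendicular to the deep aponeurosis (the muscle's
#' line-of-action reference) at positions sampled uniformly along it. The
#' ROI is expressed as a range along the deep aponeurosis direction,
#' relative to the projection of the deep point-cloud centroid.
#'
#' @param superficial,deep n x 2 point matrices (mm).
#' @param roi length-2 range (mm) along the deep aponeurosis; defaults to
#'   the extent of the deep points.
#' @param n_samples number of uniformly spaced sampling stations.
#' @return mean thickness in mm.
#' @export
muscle_thickness <- function(superficial, deep, roi = NULL, n_samples = 101L) {
  ld <- fit_line_tls(deep)
  ls <- fit_line_tls(superficial)
  if (is.null(roi)) {
    u <- as_points(deep) %*% ld$dir - sum(ld$point * ld$dir)
    roi <- range(u)
  }
  if (length(roi) != 2L || !all(is.finite(roi)) || diff(range(roi)) <= 0)
    af_stop("region of interest must have positive width",
            "archforce_input_error")
  nrm <- c(-ld$dir[2], ld$dir[1])
  # solve p + s * nrm on the superficial line for each station p
  dn <- ls$dir[1] * nrm[2] - ls$dir[2] * nrm[1]
  if (abs(dn) < 1e-12)
    af_stop("superficial aponeurosis parallel to the deep normal",
            "archforce_geometry_error")
  stations <- seq(roi[1], roi[2], length.out = n_samples)
  s <- vapply(stations, function(u) {
    p <- ld$point + u * ld$dir
    dp <- p - ls$point
    (ls$dir[1] * dp[2] - ls$dir[2] * dp[1]) / dn
  }, numeric(1))
  if (min(s) < 0 && max(s) > 0)
    af_stop("aponeuroses cross inside the region of interest",
            "archforce_geometry_error")
  mean(abs(s))
}

#' Composite fascicle from panoramic fragment orientations
#'
#' Panoramic (extended-field-of-view) scans show many short fascicle
#' fragments rather than one continuous fascicle. This reconstruction takes
#' the dominant fragment orientation of the deep region and of the
#' superficial region (angles relative to the deep aponeurosis, degrees),
#' anchors a curve on the deep aponeurosis, and integrates a composite
#' fascicle whose inclination blends linearly from the deep to the
#' superficial orientation across the inter-aponeurosis depth. Fascicle
#' length is the arc length of that curve between the aponeuroses,
#' pennation is the deep-region orientation against the deep aponeurosis,
#' and thickness is the mean inter-aponeurosis distance over the ROI.
#'
#' For equal deep and superficial orientations the composite is an exact
#' straight line (length `thickness / sin(angle)`); for differing
#' orientations the arc length lies strictly between the two straight-line
#' candidates.
#'
#' @param superficial_fragments,deep_fragments numeric vectors of fragment
#'   orientation angles (degrees, measured against the deep aponeurosis,
#'   in (0, 90)); the dominant orientation is their mean.
#' @param superficial_apo,deep_apo n x 2 point matrices of the aponeuroses.
#' @param spline_settings list; `n_steps` controls the integration
#'   resolution of the composite curve.
#' @param start_u anchor position of the composite fascicle along the deep
#'   aponeurosis (mm, relative to the deep centroid projection).
#' @param condition condition label stored in the result.
#' @return an [architecture_measure()].
#' @export
#' @examples
#' deep <- cbind(c(0, 80), c(0, 0)); sup <- cbind(c(0, 80), c(21, 21))
#' m <- composite_fascicle_panoramic(15, 15, sup, deep)
#' m$fascicle_length   # 21 / sin(15 deg) = 81.14 mm
composite_fascicle_panoramic <- function(superficial_fragments, deep_fragments,
                                         superficial_apo, deep_apo,
                                         spline_settings = list(n_steps = 4000L),
                                         start_u = 0, condition = "REST_0") {
  if (length(deep_fragments) < 1L || length(superficial_fragments) < 1L)
    af_stop("at least one fragment orientation per region is required",
            "archforce_input_error")
  th_deep <- mean(deep_fragments)
  th_sup <- mean(superficial_fragments)
  if (th_deep <= 0 || th_deep >= 90 || th_sup <= 0 || th_sup >= 90)
    af_stop("fragment orientations must lie in (0, 90) degrees",
            "archforce_reconstruction_error")
  ld <- fit_line_tls(deep_apo)
  ls <- fit_line_tls(superficial_apo)

  # work in the deep-aponeurosis frame: deep apo = x axis, superficial side up
  nrm <- c(-ld$dir[2], ld$dir[1])
  sup_ctr_local <- c(sum((ls$point - ld$point) * ld$dir),
                     sum((ls$point - ld$point) * nrm))
  if (sup_ctr_local[2] < 0) nrm <- -nrm
  to_local <- function(p) cbind(as_points(p) %*% ld$dir - sum(ld$point * ld$dir),
                                as_points(p) %*% nrm - sum(ld$point * nrm))
  sup_l <- to_local(superficial_apo)
  sfit <- stats::lm.fit(cbind(1, sup_l[, 1]), sup_l[, 2])
  alpha <- sfit$coefficients[1]; beta <- sfit$coefficients[2]
  if (alpha + beta * start_u <= 0)
    af_stop("aponeuroses cross at the composite anchor",
            "archforce_geometry_error")

  n_steps <- spline_settings$n_steps %||% 4000L
  x <- start_u; y <- 0; arc <- 0
  gap0 <- alpha + beta * x
  dy <- gap0 / n_steps
  x_limit <- abs(start_u) + 20 * gap0 + diff(range(to_local(deep_apo)[, 1]))
  repeat {
    gap <- alpha + beta * x
    if (gap <= 0 || abs(x) > x_limit)
      af_stop("composite fascicle exits the muscle: inconsistent orientations",
              "archforce_reconstruction_error")
    u <- min(1, y / gap)
    th <- deg2rad(th_deep + (th_sup - th_deep) * u)
    dx <- dy / tan(th)
    y_next <- y + dy
    gap_next <- alpha + beta * (x + dx)
    if (y_next >= gap_next) {
      # partial final step up to the superficial aponeurosis
      f <- (alpha + beta * x - y) / (dy - beta * dx)
      f <- max(0, min(1, f))
      arc <- arc + f * dy / sin(th)
      break
    }
    x <- x + dx; y <- y_next
    arc <- arc + dy / sin(th)
  }
  architecture_measure(condition = condition,
                       fascicle_length = arc,
                       pennation = th_deep,
                       thickness = muscle_thickness(superficial_apo, deep_apo))
}

#' Architecture measurement for one condition
#'
#' Fascicle length, pennation angle and muscle thickness of one participant
#' in one measurement condition: `REST_0` (panoramic scan, knee fully
#' extended, at rest), `REST_60` (dual-probe scan at 60 deg flexion, at
#' rest) or `MVC_60` (dual-probe scan at 60 deg flexion during maximum
#' contraction).
#'
#' @param condition one of `"REST_0"`, `"REST_60"`, `"MVC_60"`.
#' @param fascicle_length fascicle length, mm.
#' @param pennation pennation angle against the deep aponeurosis, degrees.
#' @param thickness mean inter-aponeurosis distance, mm.
#' @return an object of class `"architecture_measure"` (a named list).
#' @export
architecture_measure <- function(condition, fascicle_length, pennation,
                                 thickness) {
  condition <- match.arg(condition, c("REST_0", "REST_60", "MVC_60"))
  if (fascicle_length <= 0 || thickness <= 0 || pennation <= 0 ||
      pennation >= 90)
    af_stop("architecture values must be positive with pennation < 90 deg",
            "archforce_input_error")
  structure(list(condition = condition,
                 fascicle_length = as.numeric(fascicle_length),
                 pennation = as.numeric(pennation),
                 thickness = as.numeric(thickness)),
            class = "architecture_measure")
}
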