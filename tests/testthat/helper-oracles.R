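# Independent oracles and small fixtures used across the suite.

.xcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Independent torsion oracle: project the outer bonds onto the plane
# perpendicular to the central bond and take the signed angle between the
# projections (hand-derived; a different formulation from the two-normal
# atan2 used by the package).
oracle_torsion <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  bhat <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * bhat) * bhat
  v <- (p4 - p3) - sum((p4 - p3) * bhat) * bhat
  ang <- atan2(sum(.xcross(u, v) * bhat), sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# random proper rigid motion (rotation + translation)
random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 5))
}

# a generic, non-degenerate random quadruple of points
random_quadruple <- function() {
  repeat {
    ps <- lapply(1:4, function(i) rnorm(3, sd = 2))
    ok <- tryCatch({
      torsion_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(ps)
  }
}

# invert a crystal structure through the origin (Cartesian frame)
mirror_structure <- function(st) {
  xyz <- invert_through_origin(cartesian_coordinates(st))
  if (st$fractional) xyz <- cartesian_to_fractional(st$cell, xyz)
  st$atoms$x <- xyz[, 1]
  st$atoms$y <- xyz[, 2]
  st$atoms$z <- xyz[, 3]
  st
}

torsion_cols <- c("theta1", "tauF", "tauSp", "tauAp", "tauH", "theta2", "tauOMe")

# circular absolute difference in degrees
circ_diff <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 360 - d)
}

# hand-built reference tetrahedron for the C2 stereodescriptor: with the
# lowest-priority substituent (phenyl ipso) pointing away from the viewer,
# the O2 -> CF3 -> amide-C sequence runs clockwise, i.e. the R descriptor.
reference_r_tetrahedron <- function() {
  atoms <- data.frame(
    label = c("C2", "O2", "C3", "C1", "C5"),
    element = c("C", "O", "C", "C", "C"),
    x = c(0, 0, 0.866, -0.866, 0),
    y = c(0, 1, -0.5, -0.5, 0),
    z = c(0, 0.5, 0.5, 0.5, -1),
    stringsAsFactors = FALSE)
  st <- crystal_structure("ref_R", atoms)
  rolemap <- list(C2 = 1L, O2 = 2L, C3 = 3L, C1 = 4L, C5 = 5L)
  list(structure = st, rolemap = rolemap)
}

# minimal benzene molecule (no MTPA amide anywhere)
benzene_structure <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  atoms <- data.frame(
    label = c(paste0("C", 1:6), paste0("H", 1:6)),
    element = rep(c("C", "H"), each = 6),
    x = c(1.39 * cos(ang), 2.47 * cos(ang)),
    y = c(1.39 * sin(ang), 2.47 * sin(ang)),
    z = 0,
    stringsAsFactors = FALSE)
  crystal_structure("benzene", atoms)
}
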