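# Exact 3-D vector geometry: signed torsion angles (IUPAC/Klyne-Prelog
# convention), unit-cell transforms and the point-inversion (mirror) operator.

#' Wrap an angle into (-180, +180]
#'
#' All torsion angles in the package live on the half-open interval
#' (-180, +180] degrees; a computed value of exactly -180 is reported as +180
#' so that every angle has a single representation.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped into (-180, +180]. `NA` passes through.
#' @export
#' @examples
#' wrap_angle(c(-180, 190, 360, 180))
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps the seam -180 to itself; report it as +180
  w[!is.na(w) & w <= -180] <- 180
  w
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(a) sqrt(sum(a * a))

#' Signed torsion (dihedral) angle of four points
#'
#' Computes the torsion angle p1-p2-p3-p4 in degrees with the
#' IUPAC/Klyne-Prelog sign convention: looking from p2 towards p3, the angle
#' is positive when the front bond p2-p1 must be rotated clockwise onto the
#' rear bond p3-p4. Implemented with the two-plane-normal atan2 formulation,
#' which is numerically stable near 0 and 180 degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 Cartesian coordinates (angstrom).
#' @param labels optional character vector of four atom names used in error
#'   messages when the geometry is degenerate.
#' @return signed torsion angle in degrees, in (-180, +180].
#' @export
#' @examples
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   #   0 (cis)
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180 (anti)
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))   # -90
torsion_angle <- function(p1, p2, p3, p4, labels = NULL) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nm <- function(i) if (is.null(labels)) paste0("p", i) else labels[i]
  if (.norm3(b2) < 1e-12) {
    stop("degenerate geometry: coincident axis points ", nm(2), " and ", nm(3))
  }
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-10 * .norm3(b1) * .norm3(b2)) {
    stop("degenerate geometry: collinear atoms ", nm(1), ", ", nm(2), ", ", nm(3))
  }
  if (.norm3(n2) < 1e-10 * .norm3(b2) * .norm3(b3)) {
    stop("degenerate geometry: collinear atoms ", nm(2), ", ", nm(3), ", ", nm(4))
  }
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / .norm3(b2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Construct a validated unit cell
#'
#' @param a,b,c cell edge lengths in angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return an object of class `unit_cell` (named numeric vector).
#' @export
#' @examples
#' unit_cell(10, 20, 30)           # orthorhombic
#' unit_cell(7, 9, 11, 80, 95, 103) # triclinic
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(cell))) stop("invalid cell: non-finite parameter")
  if (any(cell[1:3] <= 0)) stop("invalid cell: edge lengths must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) {
    stop("invalid cell: angles must lie in (0, 180) degrees")
  }
  m <- cell_matrix_unchecked(cell)
  if (!is.finite(det(m)) || det(m) <= 0) stop("invalid cell: volume <= 0")
  class(cell) <- "unit_cell"
  cell
}

cell_matrix_unchecked <- function(cell) {
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  sg <- sin(cell[["gamma"]] * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) return(matrix(NaN, 3, 3))
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  matrix(c(
    a, b * cg, cc * cb,
    0, b * sg, cc * (ca - cb * cg) / sg,
    0, 0,      cc * sqrt(v2) / sg
  ), nrow = 3, byrow = TRUE)
}

#' Orthogonalization matrix of a unit cell
#'
#' Returns the standard 3x3 crystallographic matrix M such that
#' `M %*% frac` gives Cartesian coordinates in angstrom (a along x,
#' b in the xy-plane).
#'
#' @param cell a `unit_cell`.
#' @return 3x3 numeric matrix.
#' @export
cell_matrix <- function(cell) {
  if (!inherits(cell, "unit_cell")) cell <- do.call(unit_cell, as.list(unclass(cell)))
  cell_matrix_unchecked(cell)
}

#' Metric tensor of a unit cell
#'
#' G = t(M) M, so squared distances in fractional space are
#' `t(df) %*% G %*% df`. Used as an independent check on
#' [fractional_to_cartesian()].
#'
#' @param cell a `unit_cell`.
#' @return 3x3 numeric matrix (angstrom^2).
#' @export
metric_tensor <- function(cell) {
  m <- cell_matrix(cell)
  t(m) %*% m
}

#' Fractional to Cartesian coordinates
#'
#' @param cell a `unit_cell`.
#' @param frac numeric length-3 fractional coordinate, or an n x 3 matrix.
#' @return Cartesian coordinates (angstrom), same shape as `frac`.
#' @export
#' @examples
#' fractional_to_cartesian(unit_cell(10, 20, 30), c(0.5, 0.5, 0.5))
fractional_to_cartesian <- function(cell, frac) {
  m <- cell_matrix(cell)
  if (is.matrix(frac)) {
    t(m %*% t(frac))
  } else {
    as.numeric(m %*% frac)
  }
}

#' Cartesian to fractional coordinates
#'
#' Inverse of [fractional_to_cartesian()].
#'
#' @param cell a `unit_cell`.
#' @param cart numeric length-3 Cartesian coordinate, or an n x 3 matrix.
#' @return fractional coordinates, same shape as `cart`.
#' @export
cartesian_to_fractional <- function(cell, cart) {
  m <- solve(cell_matrix(cell))
  if (is.matrix(cart)) {
    t(m %*% t(cart))
  } else {
    as.numeric(m %*% cart)
  }
}

#' Invert points through the origin
#'
#' The mirror operator behind enantiomer normalization: every coordinate is
#' negated, turning an R-acid moiety into its S-acid mirror image (and vice
#' versa) and negating every torsion angle. Applying it twice is the identity.
#'
#' @param points numeric length-3 vector, an n x 3 matrix, or a list of
#'   length-3 vectors.
#' @return same shape as the input, with all components negated.
#' @export
#' @examples
#' invert_through_origin(c(1, 2, 3))
invert_through_origin <- function(points) {
  if (is.list(points)) lapply(points, function(p) -p) else -points
}
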