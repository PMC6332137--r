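test_that("torsion_angle reproduces the canonical cis/anti/perpendicular cases", {
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)), -90)
  # the seam is single-valued: exactly anti reports +180, never -180
  expect_gt(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 0)
})

test_that("torsion_angle agrees with the independent projection oracle", {
  set.seed(101)
  for (i in 1:300) {
    ps <- random_quadruple()
    expect_equal(torsion_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]]),
                 oracle_torsion(ps[[1]], ps[[2]], ps[[3]], ps[[4]]),
                 tolerance = 1e-11)
  }
})

test_that("torsion_angle is invariant under proper rigid motions", {
  set.seed(102)
  for (i in 1:50) {
    ps <- random_quadruple()
    rt <- random_rigid_motion()
    moved <- lapply(ps, function(p) as.numeric(rt$R %*% p + rt$t))
    expect_equal(torsion_angle(moved[[1]], moved[[2]], moved[[3]], moved[[4]]),
                 torsion_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]]),
                 tolerance = 1e-9)
  }
})

test_that("torsion_angle has reversal symmetry and inversion antisymmetry", {
  set.seed(103)
  for (i in 1:50) {
    ps <- random_quadruple()
    t0 <- torsion_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    expect_equal(torsion_angle(ps[[4]], ps[[3]], ps[[2]], ps[[1]]), t0,
                 tolerance = 1e-10)
    inv <- invert_through_origin(ps)
    ti <- torsion_angle(inv[[1]], inv[[2]], inv[[3]], inv[[4]])
    expect_equal(ti, wrap_angle(-t0), tolerance = 1e-10)
  }
})

test_that("degenerate torsion geometry raises informative errors", {
  expect_error(
    torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 0),
                  labels = c("A", "B", "C", "D")),
    "coincident.*B.*C")
  expect_error(
    torsion_angle(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)),
    "collinear")
})

test_that("fractional_to_cartesian handles orthogonal cells componentwise", {
  expect_equal(fractional_to_cartesian(unit_cell(10, 20, 30), c(0.5, 0.5, 0.5)),
               c(5, 10, 15))
  expect_equal(fractional_to_cartesian(unit_cell(10, 10, 10), c(0, 0, 0)),
               c(0, 0, 0))
})

test_that("triclinic transform matches the textbook matrix and the metric tensor", {
  cell <- unit_cell(7, 9, 11, 80, 95, 103)
  # independent construction of the orthogonalization matrix
  ca <- cos(80 * pi / 180); cb <- cos(95 * pi / 180); cg <- cos(103 * pi / 180)
  sg <- sin(103 * pi / 180)
  vol <- 7 * 9 * 11 * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  m <- matrix(c(7, 9 * cg, 11 * cb,
                0, 9 * sg, 11 * (ca - cb * cg) / sg,
                0, 0, vol / (7 * 9 * sg)), 3, 3, byrow = TRUE)
  f <- c(0.25, 0.5, 0.75)
  expect_equal(fractional_to_cartesian(cell, f), as.numeric(m %*% f),
               tolerance = 1e-12)
  # distances agree with the metric-tensor formulation to 1e-9 A
  set.seed(104)
  g <- metric_tensor(cell)
  for (i in 1:25) {
    f1 <- runif(3); f2 <- runif(3)
    d_cart <- sqrt(sum((fractional_to_cartesian(cell, f1) -
                        fractional_to_cartesian(cell, f2))^2))
    df <- f1 - f2
    d_metric <- sqrt(as.numeric(t(df) %*% g %*% df))
    expect_equal(d_cart, d_metric, tolerance = 1e-9)
  }
  # roundtrip through cartesian_to_fractional
  expect_equal(cartesian_to_fractional(cell, fractional_to_cartesian(cell, f)),
               f, tolerance = 1e-12)
})

test_that("degenerate cells are rejected", {
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, 0, 90, 90), "angles")
  # angle combination with no real volume
  expect_error(unit_cell(10, 10, 10, 170, 10, 90), "volume")
})

test_that("invert_through_origin is an involution and negates components", {
  expect_equal(invert_through_origin(c(1, 2, 3)), c(-1, -2, -3))
  pts <- list(c(1, 2, 3), c(-4, 0, 2.5))
  expect_equal(invert_through_origin(invert_through_origin(pts)), pts)
})

test_that("wrap_angle maps onto (-180, 180] with +180 at the seam", {
  expect_equal(wrap_angle(c(-180, 180, 190, -190, 360, 540)),
               c(180, 180, -170, 170, 0, 180))
})
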