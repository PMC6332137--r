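analyze_one <- function(st) {
  b <- perceive_bonds(st)
  rm1 <- assign_sp_ap(st, b, find_mtpa_moieties(st, b)[[1]])
  list(bonds = b, rolemap = rm1, ts = compute_torsion_set(st, b, rm1))
}

test_that("select_f3 picks the fluorine antiperiplanar to C1", {
  st <- build_mtpa_amide(torsion_spec(tauF = -174))
  a <- analyze_one(st)
  expect_equal(a$ts$tauF, -174, tolerance = 1e-6)
  # the other two fluorines sit at -54 and +66: F3 maximizes |torsion|
  xyz <- cartesian_coordinates(st)
  rm1 <- a$rolemap
  all_tors <- vapply(rm1$F_all, function(f) {
    torsion_angle(xyz[rm1$C1, ], xyz[rm1$C2, ], xyz[rm1$C3, ], xyz[f, ])
  }, numeric(1))
  expect_equal(sort(round(all_tors)), c(-174, -54, 66))
  expect_equal(max(abs(all_tors)), abs(a$ts$tauF), tolerance = 1e-9)
})

test_that("CF3 selection yields |tauF| >= 120 and ~120-degree spacing for any rotation", {
  set.seed(201)
  for (rot in runif(12, -180, 180)) {
    st <- build_mtpa_amide(torsion_spec(tauF = wrap_angle(rot)))
    a <- analyze_one(st)
    expect_gte(abs(a$ts$tauF), 120)
    xyz <- cartesian_coordinates(st)
    rm1 <- a$rolemap
    tors <- sort(vapply(rm1$F_all, function(f) {
      torsion_angle(xyz[rm1$C1, ], xyz[rm1$C2, ], xyz[rm1$C3, ], xyz[f, ])
    }, numeric(1)))
    gaps <- c(diff(tors), 360 - (tors[3] - tors[1]))
    expect_true(all(abs(gaps - 120) <= 2))
  }
})

test_that("select_c10 picks the ortho carbon with the smaller |torsion|", {
  st <- build_mtpa_amide(torsion_spec(theta2 = 21))
  a <- analyze_one(st)
  expect_equal(a$ts$theta2, 21, tolerance = 1e-6)
  xyz <- cartesian_coordinates(st)
  rm1 <- a$rolemap
  both <- vapply(rm1$ortho_pair, function(cc) {
    torsion_angle(xyz[rm1$O2, ], xyz[rm1$C2, ], xyz[rm1$C5, ], xyz[cc, ])
  }, numeric(1))
  expect_equal(sort(round(both)), c(-159, 21))
  # planar ring: the two ortho torsions differ by 180 +/- 3 degrees
  expect_lte(abs(circ_diff(both[1], both[2]) - 180), 3)
  # |theta2| <= 90 for any phenyl twist
  set.seed(202)
  for (rot in runif(8, -90, 90)) {
    a2 <- analyze_one(build_mtpa_amide(torsion_spec(theta2 = rot)))
    expect_lte(abs(a2$ts$theta2), 90)
  }
})

test_that("compute_torsion_set recovers generator targets within 0.5 degrees", {
  sp <- torsion_spec(theta1 = -13, tauF = -174, tauSp = 2, tauAp = -174,
                     tauH = -11, theta2 = 21, tauOMe = 54)
  a <- analyze_one(build_mtpa_amide(sp))
  got <- unlist(a$ts[c("theta1", "tauF", "tauSp", "tauH", "theta2", "tauOMe")])
  want <- c(-13, -174, 2, -11, 21, 54)
  expect_true(all(circ_diff(got, want) <= 0.5))
  expect_equal(a$ts$chirality, "R")
  # secondary amide: R^ap = H means tauAp is null, never the N-H torsion
  expect_true(is.na(a$ts$tauAp))
  expect_equal(a$ts$arity, "secondary")
})

test_that("mirror-image input negates every non-null torsion", {
  st <- build_mtpa_amide(torsion_spec(amine_template = "N_methyl_isopropyl",
                                      theta1 = -25, tauSp = 8, tauAp = -170))
  a <- analyze_one(st)
  am <- analyze_one(mirror_structure(st))
  for (d in torsion_cols) {
    if (is.na(a$ts[[d]])) {
      expect_true(is.na(am$ts[[d]]))
    } else {
      expect_equal(am$ts[[d]], wrap_angle(-a$ts[[d]]), tolerance = 1e-8)
    }
  }
  expect_equal(am$ts$chirality, "S")
})

test_that("normalize_to_R negates S records once and is idempotent", {
  ts <- structure(list(theta1 = 35, tauF = 165.9, tauSp = 0.5, tauAp = -179.5,
                       tauH = 15.2, theta2 = -43.7, tauOMe = -72,
                       chirality = "S", normalized = FALSE),
                  class = "torsion_set")
  n1 <- normalize_to_R(ts)
  expect_equal(n1$theta1, -35)
  expect_equal(n1$tauAp, 179.5)
  expect_equal(n1$chirality, "R")
  expect_true(n1$normalized)
  expect_identical(normalize_to_R(n1), n1)
  # +180 is the fixed point of the sign reversal
  ts$theta1 <- 180
  expect_equal(normalize_to_R(ts)$theta1, 180)
  # R records pass through unchanged
  tsr <- ts; tsr$chirality <- "R"
  expect_equal(normalize_to_R(tsr)$theta1, tsr$theta1)
})

test_that("normalize_rows mirrors the S rows of the reference table", {
  t1 <- load_table1()
  rows <- normalize_rows(t1)
  expect_equal(rows$theta1[4], -35.0)   # an S record printed as +35.0
  expect_equal(rows$theta1[50], -57)    # +57 printed, -57 as R-acid enantiomer
  expect_equal(rows$theta1[1], t1$theta1[1])  # R rows unchanged
  expect_true(all(rows$chirality == "R"))
  expect_equal(rows$chirality_printed, t1$chirality)
  expect_identical(normalize_rows(rows), rows)
})

test_that("conformer classification reproduces the reference-row categories", {
  rows <- classify_rows(load_table1())
  r1 <- rows[1, ]
  expect_equal(r1$theta1_window, "sp_major")
  expect_true(r1$cf3_staggered)
  expect_equal(r1$amide_form, "Z")
  expect_true(r1$mosher_type)
  expect_equal(r1$carbonyl_methoxy, "syn")
  # the footnote-f conformer with theta1 -67.7 and tauOMe -162.7
  expect_equal(rows$theta1_window[9], "minor_anti")
  expect_equal(rows$carbonyl_methoxy[9], "anti")
  # N-methyl rows are E
  expect_equal(rows$amide_form[26], "E")
  # anti rows are exactly the footnote-f rows
  expect_equal(rows$row_no[rows$carbonyl_methoxy == "anti"],
               rows$row_no[has_flag(rows, "f")])
  # sp_major membership matches the windowed-mean bookkeeping: 48 rows
  expect_equal(sum(rows$theta1 > -30 & rows$theta1 <= 0), 48)
})

test_that("classification demands normalized input", {
  ts <- list(theta1 = -13, tauF = -174, tauOMe = 54, normalized = FALSE,
             arity = "secondary")
  expect_error(classify_conformer(ts, "secondary_alkyl", "H"), "normalized")
})
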