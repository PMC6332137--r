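test_that("noise-free builds hit every supported torsion target exactly", {
  cases <- list(
    list(tmpl = "isopropylamine",
         targets = c(theta1 = -13, tauF = -174, tauSp = 2, tauH = -11,
                     theta2 = 21, tauOMe = 54)),
    list(tmpl = "isopropylamine",
         targets = c(theta1 = 30, tauF = 155, tauSp = -25, tauH = 170,
                     theta2 = -60, tauOMe = -120)),
    list(tmpl = "n_propylamine",
         targets = c(theta1 = -26, tauF = -168, tauSp = -6, theta2 = 24,
                     tauOMe = 72)),
    list(tmpl = "pyrrolidine",
         targets = c(theta1 = -4.7, tauF = -175.4, tauSp = 5.3, theta2 = 27.5,
                     tauOMe = 53.4)),
    list(tmpl = "N_methyl_isopropyl",
         targets = c(theta1 = 8.6, tauF = 173.1, tauSp = 0.1, tauAp = 173.6,
                     theta2 = -12.7, tauOMe = -50)),
    list(tmpl = "tetrakis_aryl",
         targets = c(theta1 = -17, tauF = -174.9, tauSp = -11, theta2 = 8,
                     tauOMe = 54.6)))
  for (cs in cases) {
    args <- c(as.list(cs$targets), list(amine_template = cs$tmpl))
    st <- build_mtpa_amide(do.call(torsion_spec, args))
    rows <- analyze_structure(st, normalize = FALSE)
    for (d in names(cs$targets)) {
      for (v in rows[[d]]) {
        expect_lte(circ_diff(v, cs$targets[[d]]), 0.5)
      }
    }
  }
})

test_that("unsupported targets and invalid specs are rejected", {
  expect_error(torsion_spec(tauH = 10, amine_template = "pyrrolidine"),
               "does not support a tauH")
  expect_error(torsion_spec(tauAp = -170, amine_template = "tetrakis_aryl"),
               "does not support a tauAp")
  expect_error(torsion_spec(theta1 = 200), "outside")
  expect_error(torsion_spec(chirality = "Q"), "chirality")
  expect_error(torsion_spec(amine_template = "anything"), "unknown amine template")
  expect_error(torsion_spec(noise_sigma = -1), "noise_sigma")
})

test_that("S builds measure as the negated torsions and normalize identically", {
  spR <- torsion_spec(theta1 = -22, tauSp = 7, tauH = -30, theta2 = 35, chirality = "R")
  spS <- torsion_spec(theta1 = -22, tauSp = 7, tauH = -30, theta2 = 35, chirality = "S")
  rawR <- analyze_structure(build_mtpa_amide(spR), normalize = FALSE)
  rawS <- analyze_structure(build_mtpa_amide(spS), normalize = FALSE)
  expect_equal(rawR$chirality, "R")
  expect_equal(rawS$chirality, "S")
  for (d in torsion_cols) {
    if (!is.na(rawR[[d]])) {
      expect_equal(rawS[[d]], wrap_angle(-rawR[[d]]), tolerance = 1e-8)
    }
  }
  nR <- classify_rows(rawR)
  nS <- classify_rows(rawS)
  expect_equal(nS[, torsion_cols], nR[, torsion_cols], tolerance = 1e-8)
  expect_equal(nS$amide_form, nR$amide_form)
})

test_that("the pyrrolidine template realizes the cyclic secondary-amine Z form", {
  rows <- analyze_structure(build_mtpa_amide(torsion_spec(amine_template = "pyrrolidine")))
  expect_equal(rows$arity, "tertiary")
  expect_equal(rows$rsp_class, "secondary_alkyl")
  expect_equal(rows$rap_class, "primary_alkyl")
  expect_equal(rows$amide_form, "Z")
})

test_that("perturbation is deterministic, seed-scoped and vanishes at sigma 0", {
  st <- build_mtpa_amide(torsion_spec())
  expect_identical(perturb_structure(st, 0, seed = 5), st)
  p1 <- perturb_structure(st, 0.02, seed = 7)
  p2 <- perturb_structure(st, 0.02, seed = 7)
  expect_identical(p1$atoms, p2$atoms)
  p3 <- perturb_structure(st, 0.02, seed = 8)
  expect_false(identical(p1$atoms, p3$atoms))
  # rms displacement matches the sigma convention (rms magnitude per atom)
  d <- sqrt(rowSums((cartesian_coordinates(p1) - cartesian_coordinates(st))^2))
  expect_equal(sqrt(mean(d^2)), 0.02, tolerance = 0.5)
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(perturb_structure(st, 0.02, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("sample_survey is deterministic and recovers its sampling parameters", {
  s1 <- sample_survey(1, seed = 4)
  expect_length(s1, 1)
  a <- sample_survey(20, seed = 11)
  b <- sample_survey(20, seed = 11)
  expect_identical(lapply(a, `[[`, "atoms"), lapply(b, `[[`, "atoms"))
  targets <- attr(a, "targets")
  # after R-frame normalization the recovered torsions equal the drawn
  # targets for R and S structures alike
  rows <- do.call(rbind, lapply(a, analyze_structure))
  for (d in c("theta1", "tauSp", "theta2", "tauOMe", "tauH")) {
    expect_true(all(circ_diff(rows[[d]], targets[[d]]) <= 0.5))
  }
  # an all-S sample normalizes to the same survey as the all-R sample
  rs <- sample_survey(15, chirality = "R", seed = 21)
  ss <- sample_survey(15, chirality = "S", seed = 21)
  svR <- survey_structures(rs)
  svS <- survey_structures(ss)
  expect_equal(svS$panel, svR$panel)
  expect_true(all(do.call(rbind, lapply(ss, analyze_structure,
                                        normalize = FALSE))$chirality == "S"))
})

test_that("builds pass through CIF serialization without descriptor drift", {
  st <- build_mtpa_amide(torsion_spec(theta1 = -19, theta2 = 33))
  tmp <- tempfile(fileext = ".cif")
  write_cif(st, tmp)
  rows <- analyze_structure(read_cif(tmp)[[1]], normalize = FALSE)
  expect_equal(rows$theta1, -19, tolerance = 1e-3)
  expect_equal(rows$theta2, 33, tolerance = 1e-3)
})
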