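pair_structure <- function(d, elements = c("C", "C")) {
  crystal_structure("pair", data.frame(
    label = paste0(elements, 1:2), element = elements,
    x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE))
}

test_that("bond perception follows the covalent-radius cutoff", {
  b <- perceive_bonds(pair_structure(1.54))
  expect_equal(bonded_neighbors(b, 1), 2L)         # C-C 1.54 A is bonded
  b2 <- perceive_bonds(pair_structure(2.50))
  expect_length(bonded_neighbors(b2, 1), 0)        # 2.5 A is not
  expect_error(perceive_bonds(pair_structure(0.3)), "overlapping")
  # the H cap: C-H at 1.09 bonded, at 1.35 not (within radius sum but > cap)
  bh <- perceive_bonds(pair_structure(1.09, c("C", "H")))
  expect_equal(bonded_neighbors(bh, 1), 2L)
  bh2 <- perceive_bonds(pair_structure(1.35, c("C", "H")))
  expect_length(bonded_neighbors(bh2, 1), 0)
})

test_that("generator structures have the expected coordination at C2 and C3", {
  st <- build_mtpa_amide(torsion_spec())
  b <- perceive_bonds(st)
  maps <- find_mtpa_moieties(st, b)
  expect_length(maps, 1)
  rm1 <- maps[[1]]
  hv_c2 <- setdiff(bonded_neighbors(b, rm1$C2),
                   which(b$elements == "H"))
  expect_length(hv_c2, 4)
  expect_setequal(hv_c2, c(rm1$C1, rm1$C3, rm1$O2, rm1$C5))
  expect_length(rm1$F_all, 3)
  expect_setequal(bonded_neighbors(b, rm1$C3), c(rm1$C2, rm1$F_all))
  # no self-bonds anywhere
  expect_false(any(vapply(seq_len(b$n), function(i) i %in% bonded_neighbors(b, i),
                          logical(1))))
})

test_that("moiety matching finds every arm and nothing else", {
  st4 <- build_mtpa_amide(torsion_spec(amine_template = "tetrakis_aryl"))
  expect_length(find_mtpa_moieties(st4), 4)
  expect_length(find_mtpa_moieties(benzene_structure()), 0)
})

test_that("sp/ap lateralization follows the |torsion| <= 90 rule", {
  st <- build_mtpa_amide(torsion_spec(amine_template = "N_methyl_isopropyl",
                                      tauSp = 3, tauAp = -176))
  b <- perceive_bonds(st)
  rm1 <- assign_sp_ap(st, b, find_mtpa_moieties(st, b)[[1]])
  expect_equal(substituent_class(st, b, rm1$C1p), "methyl")
  expect_equal(substituent_class(st, b, rm1$X1pp), "secondary_alkyl")
  expect_equal(rm1$n_amide_h, 0)
  # secondary amide: the ap hydrogen leaves X1pp null and R^ap = H
  st2 <- build_mtpa_amide(torsion_spec(tauSp = 2, tauAp = -173))
  b2 <- perceive_bonds(st2)
  rm2 <- assign_sp_ap(st2, b2, find_mtpa_moieties(st2, b2)[[1]])
  expect_true(is.na(rm2$X1pp))
  expect_true(rm2$rap_is_H)
  expect_equal(rm2$n_amide_h, 1)
  expect_equal(substituent_class(st2, b2, rm2$C1p), "secondary_alkyl")
})

test_that("near-boundary lateralization still assigns, with a warning", {
  st <- build_mtpa_amide(torsion_spec(amine_template = "N_methyl_isopropyl",
                                      tauSp = 89, tauAp = -91))
  b <- perceive_bonds(st)
  expect_warning(rm1 <- assign_sp_ap(st, b, find_mtpa_moieties(st, b)[[1]]),
                 "90-degree boundary")
  expect_false(is.na(rm1$C1p))
  expect_false(is.na(rm1$X1pp))
})

test_that("the C2 descriptor matches the hand-built reference tetrahedron", {
  ref <- reference_r_tetrahedron()
  expect_equal(chirality_at_c2(ref$structure, ref$rolemap), "R")
  expect_equal(chirality_at_c2(mirror_structure(ref$structure), ref$rolemap), "S")
})

test_that("the descriptor flips under inversion and matches the build target", {
  for (ch in c("R", "S")) {
    st <- build_mtpa_amide(torsion_spec(chirality = ch))
    b <- perceive_bonds(st)
    rm1 <- assign_sp_ap(st, b, find_mtpa_moieties(st, b)[[1]])
    expect_equal(chirality_at_c2(st, rm1), ch)
    stm <- mirror_structure(st)
    rm_m <- assign_sp_ap(stm, perceive_bonds(stm), find_mtpa_moieties(stm)[[1]])
    expect_equal(chirality_at_c2(stm, rm_m), setdiff(c("R", "S"), ch))
  }
})

test_that("substituent classes cover the H/alkyl chain and special classes", {
  st <- build_mtpa_amide(torsion_spec(amine_template = "n_propylamine"))
  b <- perceive_bonds(st)
  rm1 <- assign_sp_ap(st, b, find_mtpa_moieties(st, b)[[1]])
  expect_equal(substituent_class(st, b, rm1$C1p), "primary_alkyl")
  expect_equal(substituent_class(st, b, NA), "H")
  st4 <- build_mtpa_amide(torsion_spec(amine_template = "tetrakis_aryl"))
  b4 <- perceive_bonds(st4)
  rm4 <- assign_sp_ap(st4, b4, find_mtpa_moieties(st4, b4)[[1]])
  expect_equal(substituent_class(st4, b4, rm4$C1p), "aryl")
})

test_that("Z/E classification reproduces the survey's rules", {
  expect_equal(classify_amide_form("secondary_alkyl", "primary_alkyl"), "Z")
  expect_equal(classify_amide_form("methyl", "secondary_alkyl"), "E")
  expect_equal(classify_amide_form("primary_alkyl", "primary_alkyl"), "indeterminate")
  expect_equal(classify_amide_form("secondary_alkyl", "H"), "Z")
  expect_equal(classify_amide_form("aryl", "H"), "Z")             # C > H
  expect_equal(classify_amide_form("sulfonyl", "primary_alkyl"), "Z")  # S > C
  expect_equal(classify_amide_form("aryl", "nitrogen"), "E")      # N > C
  expect_equal(classify_amide_form("selenoxo", "secondary_alkyl"),
               "indeterminate")                                   # both C-alpha, unranked
})

test_that("fixture classifications reproduce the survey's tallies", {
  rows <- classify_rows(load_table1())
  tert <- rows[rows$amine_class == "secondary_amine", ]
  expect_equal(sum(tert$amide_form == "Z"), 13)
  expect_equal(sum(tert$amide_form == "E"), 4)
  expect_equal(sum(tert$amide_form == "indeterminate"), 9)
  prim <- rows[rows$amine_class == "primary_amine", ]
  expect_equal(nrow(prim), 14)
  expect_true(all(prim$amide_form == "Z"))
  expect_true(all(prim$arity == "secondary"))
  # Mosher-type rows are exactly the footnote-d rows
  expect_equal(rows$row_no[rows$mosher_type], rows$row_no[has_flag(rows, "d")])
})
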