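# The seven torsion descriptors of the survey, their atom-selection
# conventions (F3 = fluorine ap to C1, C10 = ortho carbon with the smaller
# |torsion|), mirror normalization of S-acid records to the R-acid frame, and
# the categorical conformer classification.

#' Select F3, the fluorine antiperiplanar to C1
#'
#' Among the three fluorines on the CF3 carbon, returns the one maximizing
#' |torsion(C1-C2-C3-F)|. For any near-tetrahedral CF3 the resulting
#' descriptor satisfies |tauF| >= 120 degrees. Ties within 0.01 degrees are
#' broken deterministically by atom label order (logged).
#'
#' @param structure a `crystal_structure`.
#' @param rolemap a lateralized `mtpa_roles`.
#' @return index of the selected fluorine.
#' @export
select_f3 <- function(structure, rolemap) {
  if (length(rolemap$F_all) != 3) {
    stop("role map: CF3 carbon must carry exactly three fluorines (found ",
         length(rolemap$F_all), ")")
  }
  xyz <- cartesian_coordinates(structure)
  tors <- vapply(rolemap$F_all, function(f) {
    torsion_angle(xyz[rolemap$C1, ], xyz[rolemap$C2, ], xyz[rolemap$C3, ], xyz[f, ],
                  labels = c("C1", "C2", "C3", structure$atoms$label[f]))
  }, numeric(1))
  o <- order(abs(tors), structure$atoms$label[rolemap$F_all], decreasing = TRUE)
  top <- o[1]
  if (sum(abs(abs(tors) - abs(tors[top])) <= 0.01) > 1) {
    # stable tie-break: larger |torsion| first, then label order ascending
    tied <- which(abs(abs(tors) - abs(tors[top])) <= 0.01)
    top <- tied[order(structure$atoms$label[rolemap$F_all[tied]])][1]
    message("select_f3: tie within 0.01 degrees broken by atom label order")
  }
  rolemap$F_all[top]
}

#' Select C10, the ortho carbon giving the smaller |theta2|
#'
#' Of the two ortho carbons of the phenyl ring, returns the one minimizing
#' |torsion(O2-C2-C5-C)|, which guarantees |theta2| <= 90 degrees. An exact
#' tie at 90 degrees resolves to the positive-valued torsion (logged).
#'
#' @param structure a `crystal_structure`.
#' @param rolemap a lateralized `mtpa_roles`.
#' @return index of the selected ortho carbon.
#' @export
select_c10 <- function(structure, rolemap) {
  xyz <- cartesian_coordinates(structure)
  tors <- vapply(rolemap$ortho_pair, function(cc) {
    torsion_angle(xyz[rolemap$O2, ], xyz[rolemap$C2, ], xyz[rolemap$C5, ], xyz[cc, ],
                  labels = c("O2", "C2", "C5", structure$atoms$label[cc]))
  }, numeric(1))
  if (abs(abs(tors[1]) - abs(tors[2])) < 1e-9) {
    message("select_c10: |torsion| tie at the 90-degree seam; choosing the positive torsion")
    return(rolemap$ortho_pair[which(tors > 0)[1]])
  }
  rolemap$ortho_pair[which.min(abs(tors))]
}

#' Compute the seven torsion descriptors of one MTPA-amide moiety
#'
#' theta1 = O1-C1-C2-C3, tauF = C1-C2-C3-F3, tauSp = C1'-N-C1-O1,
#' tauAp = X1''-N-C1-O1 (NA when R^ap is hydrogen), tauH = H1'-C1'-N-C1
#' (NA when no unique methine hydrogen exists), theta2 = O2-C2-C5-C10,
#' tauOMe = C1-C2-O2-C4. The as-measured chirality is recorded and
#' `normalized` is `FALSE`; see [normalize_to_R()].
#'
#' @param structure a `crystal_structure`.
#' @param bonds a `bond_graph`.
#' @param rolemap a lateralized `mtpa_roles` (after [assign_sp_ap()]).
#' @return object of class `torsion_set`: named list with the seven angles,
#'   `chirality`, `normalized`, `h1p_inferred`, and `arity`
#'   (`"secondary"`/`"tertiary"` amide).
#' @export
compute_torsion_set <- function(structure, bonds, rolemap) {
  xyz <- cartesian_coordinates(structure)
  p <- function(role) xyz[rolemap[[role]], ]
  tor <- function(a, b, c, d, what) {
    tryCatch(torsion_angle(a, b, c, d),
             error = function(e) stop("descriptor ", what, ": ", conditionMessage(e)))
  }
  theta1 <- tor(p("O1"), p("C1"), p("C2"), p("C3"), "theta1")
  f3 <- select_f3(structure, rolemap)
  tauF <- tor(p("C1"), p("C2"), p("C3"), xyz[f3, ], "tauF")
  tauSp <- if (!is.na(rolemap$C1p)) {
    tor(xyz[rolemap$C1p, ], p("N"), p("C1"), p("O1"), "tauSp")
  } else NA_real_
  tauAp <- if (!is.na(rolemap$X1pp)) {
    tor(xyz[rolemap$X1pp, ], p("N"), p("C1"), p("O1"), "tauAp")
  } else NA_real_
  tauH <- NA_real_
  if (!is.na(rolemap$H1p)) {
    tauH <- tor(xyz[rolemap$H1p, ], xyz[rolemap$C1p, ], p("N"), p("C1"), "tauH")
  } else if (isTRUE(rolemap$h1p_inferred)) {
    tauH <- tor(rolemap$H1p_xyz, xyz[rolemap$C1p, ], p("N"), p("C1"), "tauH")
  }
  c10 <- select_c10(structure, rolemap)
  theta2 <- tor(p("O2"), p("C2"), p("C5"), xyz[c10, ], "theta2")
  tauOMe <- tor(p("C1"), p("C2"), p("O2"), p("C4"), "tauOMe")
  ts <- list(theta1 = theta1, tauF = tauF, tauSp = tauSp, tauAp = tauAp,
             tauH = tauH, theta2 = theta2, tauOMe = tauOMe,
             chirality = chirality_at_c2(structure, rolemap),
             normalized = FALSE,
             h1p_inferred = isTRUE(rolemap$h1p_inferred),
             arity = if (isTRUE(rolemap$n_amide_h >= 1)) "secondary" else "tertiary",
             F3 = f3, C10 = c10)
  class(ts) <- "torsion_set"
  ts
}

# negate an angle on (-180, 180]; the +180 seam is its own mirror image
.negate_angle <- function(x) {
  y <- -x
  y[!is.na(y) & y <= -180] <- 180
  y
}

#' Normalize a torsion set to the R-acid frame
#'
#' S-acid moieties are replaced by their mirror images: every non-null angle
#' is negated (with +180 as the fixed point of the (-180, 180] convention)
#' and the record is relabeled as R-frame. R-acid input passes through
#' unchanged. Idempotent.
#'
#' @param ts a `torsion_set`.
#' @return the normalized `torsion_set` (`normalized = TRUE`).
#' @export
normalize_to_R <- function(ts) {
  if (isTRUE(ts$normalized)) return(ts)
  if (ts$chirality == "S") {
    for (col in .torsion_cols) ts[[col]] <- .negate_angle(ts[[col]])
    ts$chirality <- "R"
  }
  ts$normalized <- TRUE
  ts
}

#' Mirror-normalize a table of moiety records to the R-acid frame
#'
#' Applies the plus/minus sign reversal of [normalize_to_R()] to every
#' S-chirality row of a torsion table (the packaged reference table or the
#' output of [analyze_structure()]).
#'
#' @param rows data frame with `chirality` and the seven torsion columns.
#' @return the table with S rows negated, `chirality_printed` preserving the
#'   original descriptor and `normalized = TRUE`.
#' @export
normalize_rows <- function(rows) {
  if (!is.null(rows$normalized) && all(rows$normalized)) return(rows)
  s <- rows$chirality == "S"
  for (col in .torsion_cols) {
    if (!is.null(rows[[col]])) rows[[col]][s] <- .negate_angle(rows[[col]][s])
  }
  rows$chirality_printed <- rows$chirality
  rows$chirality <- "R"
  rows$normalized <- TRUE
  rows
}

#' Classify the conformation of one normalized moiety
#'
#' Categorical assignments used by the survey:
#' \itemize{
#' \item `theta1_window`: `"sp_major"` for -30 < theta1 <= 0 (the dominant
#'   synperiplanar window), `"minor_anti"` for the minor conformer in which
#'   carbonyl and methoxy are anti, `"other"` otherwise.
#' \item `cf3_staggered`: |tauF| >= 150 (one fluorine antiperiplanar to C1).
#' \item `carbonyl_methoxy`: `"anti"` when tauOMe leaves the +30..+80 rotamer
#'   window and |tauOMe| >= 120, else `"syn"`.
#' \item `amide_form`: Z/E/indeterminate from [classify_amide_form()].
#' \item `mosher_type`: secondary amide whose sp substituent is a secondary
#'   alkyl (the classical substrate of the NMR method).
#' }
#'
#' @param ts a normalized `torsion_set` (or a list with the torsion fields).
#' @param rsp_class,rap_class substituent classes of the two N-substituents.
#' @param amide_arity `"secondary"` or `"tertiary"`; defaults to the arity
#'   recorded in `ts`.
#' @return object of class `conformer_class` (named list).
#' @export
classify_conformer <- function(ts, rsp_class, rap_class,
                               amide_arity = ts$arity) {
  if (!isTRUE(ts$normalized)) {
    stop("classify_conformer requires a normalized torsion set; call normalize_to_R() first")
  }
  anti <- !is.na(ts$tauOMe) &&
    !(ts$tauOMe > 30 & ts$tauOMe < 80) && abs(ts$tauOMe) >= 120
  window <- if (anti) {
    "minor_anti"
  } else if (!is.na(ts$theta1) && ts$theta1 > -30 && ts$theta1 <= 0) {
    "sp_major"
  } else {
    "other"
  }
  out <- list(
    theta1_window = window,
    cf3_staggered = !is.na(ts$tauF) && abs(ts$tauF) >= 150,
    carbonyl_methoxy = if (anti) "anti" else "syn",
    amide_form = classify_amide_form(rsp_class, rap_class),
    mosher_type = identical(amide_arity, "secondary") &&
      identical(rsp_class, "secondary_alkyl"))
  class(out) <- "conformer_class"
  out
}

#' Normalize and classify a table of moiety records
#'
#' Convenience wrapper: mirror-normalizes the table, derives the amide arity
#' (secondary when R^ap is hydrogen), and appends the conformer
#' classification columns.
#'
#' @param rows a torsion table ([load_table1()] or [analyze_structure()]).
#' @return the normalized table with `arity`, `theta1_window`,
#'   `cf3_staggered`, `carbonyl_methoxy`, `amide_form`, `mosher_type` columns.
#' @export
classify_rows <- function(rows) {
  rows <- normalize_rows(rows)
  if (is.null(rows$arity)) {
    rows$arity <- ifelse(rows$rap_class == "H", "secondary", "tertiary")
  }
  n <- nrow(rows)
  cls <- lapply(seq_len(n), function(i) {
    ts <- list(theta1 = rows$theta1[i], tauF = rows$tauF[i],
               tauOMe = rows$tauOMe[i], normalized = TRUE,
               arity = rows$arity[i])
    classify_conformer(ts, rows$rsp_class[i], rows$rap_class[i], rows$arity[i])
  })
  rows$theta1_window <- vapply(cls, `[[`, "", "theta1_window")
  rows$cf3_staggered <- vapply(cls, `[[`, logical(1), "cf3_staggered")
  rows$carbonyl_methoxy <- vapply(cls, `[[`, "", "carbonyl_methoxy")
  rows$amide_form <- vapply(cls, `[[`, "", "amide_form")
  rows$mosher_type <- vapply(cls, `[[`, logical(1), "mosher_type")
  rows
}
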