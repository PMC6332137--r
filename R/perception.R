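# From raw coordinates to chemistry: covalent-radius bond perception,
# location of MTPA-amide moieties, atom-role assignment (the survey's
# C1/O1/N/C2/C3/O2/C4/C5 numbering), sp/ap lateralization of the two
# N-substituents, the C2 stereodescriptor and substituent classes.

# Cordero-style single-bond covalent radii (angstrom)
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  As = 1.19, Se = 1.20, Br = 1.20, Ru = 1.46, Rh = 1.42, Pd = 1.39,
  Ag = 1.45, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Pt = 1.36, Au = 1.36)

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed the sum of their
#' covalent radii plus 0.40 angstrom; bonds involving hydrogen are
#' additionally capped at 1.3 angstrom. Distances below 0.5 angstrom indicate
#' overlapping atoms and raise an error.
#'
#' @param structure a `crystal_structure`.
#' @return object of class `bond_graph`: list with `adjacency` (list of
#'   integer neighbor vectors), `n`, and `elements`.
#' @export
perceive_bonds <- function(structure) {
  xyz <- cartesian_coordinates(structure)
  el <- structure$atoms$element
  n <- nrow(xyz)
  r <- .covalent_radii[el]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  }
  d <- as.matrix(stats::dist(xyz))
  too_close <- d < 0.5 & upper.tri(d)
  if (any(too_close)) {
    ij <- which(too_close, arr.ind = TRUE)[1, ]
    stop("overlapping atoms (d < 0.5 A): ",
         structure$atoms$label[ij[1]], " / ", structure$atoms$label[ij[2]])
  }
  cutoff <- outer(r, r, "+") + 0.40
  h <- el == "H"
  hcap <- outer(h, h, "|")
  cutoff[hcap] <- pmin(cutoff[hcap], 1.3)
  bonded <- d <= cutoff
  diag(bonded) <- FALSE
  # H-H bonds are never chemical bonds in these structures
  bonded[outer(h, h, "&")] <- FALSE
  adjacency <- lapply(seq_len(n), function(i) unname(which(bonded[i, ])))
  structure(list(adjacency = adjacency, n = n, elements = el),
            class = "bond_graph")
}

#' Bonded neighbors of an atom
#'
#' @param bonds a `bond_graph`.
#' @param i atom index.
#' @return integer vector of neighbor indices.
#' @export
bonded_neighbors <- function(bonds, i) bonds$adjacency[[i]]

.heavy_neighbors <- function(bonds, i) {
  nb <- bonds$adjacency[[i]]
  nb[bonds$elements[nb] != "H"]
}

# is `i` a carbon inside a six-membered all-carbon ring? returns the two ring
# neighbors (ortho pair) or NULL. Depth-limited DFS; molecules here are small.
.six_carbocycle_neighbors <- function(bonds, i) {
  if (bonds$elements[i] != "C") return(NULL)
  ring_c <- function(j) bonds$elements[j] == "C"
  nbs <- .heavy_neighbors(bonds, i)
  nbs <- nbs[ring_c(nbs)]
  if (length(nbs) < 2) return(NULL)
  # search a path i - a - x - y - z - b - i of distinct carbons
  for (a in nbs) for (b in nbs) {
    if (a >= b) next
    for (x in setdiff(.heavy_neighbors(bonds, a), c(i, b))) {
      if (!ring_c(x)) next
      for (y in setdiff(.heavy_neighbors(bonds, x), c(i, a, b))) {
        if (!ring_c(y)) next
        for (z in setdiff(.heavy_neighbors(bonds, y), c(i, a, b, x))) {
          if (!ring_c(z)) next
          if (b %in% .heavy_neighbors(bonds, z)) return(c(a, b))
        }
      }
    }
  }
  NULL
}

#' Locate MTPA-amide moieties and assign atom roles
#'
#' Scans the bond graph for the MTPA-amide substructure: a quaternary carbon
#' C2 bonded to exactly a CF3 carbon (C3), a methoxy oxygen (O2, whose other
#' neighbor is the methyl C4), an amide carbonyl carbon (C1, bonded to a
#' terminal oxygen O1 and a nitrogen N) and a phenyl ipso carbon (C5, member
#' of a six-carbon ring whose two ring neighbors form the ortho pair). One
#' role map is returned per moiety, so bis/tetrakis amides yield several.
#' The sp/ap sides of the two N-substituents are not yet lateralized
#' (see [assign_sp_ap()]).
#'
#' @param structure a `crystal_structure`.
#' @param bonds the corresponding `bond_graph` (computed when omitted).
#' @return list of role maps (class `mtpa_roles`): named lists with indices
#'   `C1`, `O1`, `N`, `C2`, `C3`, `F_all`, `O2`, `C4`, `C5`, `ortho_pair`,
#'   and `C1p`/`X1pp`/`H1p` set to `NA` until lateralization.
#' @export
find_mtpa_moieties <- function(structure, bonds = perceive_bonds(structure)) {
  el <- bonds$elements
  maps <- list()
  for (c2 in which(el == "C")) {
    hv <- .heavy_neighbors(bonds, c2)
    if (length(hv) != 4) next
    # CF3 carbon: carbon neighbor whose heavy neighbors are c2 + three F
    is_cf3 <- vapply(hv, function(j) {
      el[j] == "C" && {
        hj <- .heavy_neighbors(bonds, j)
        length(hj) == 4 && sum(el[hj] == "F") == 3 && c2 %in% hj
      }
    }, logical(1))
    # methoxy oxygen: O with exactly two heavy neighbors, the other a carbon
    is_o2 <- vapply(hv, function(j) {
      el[j] == "O" && {
        hj <- .heavy_neighbors(bonds, j)
        length(hj) == 2 && any(el[setdiff(hj, c2)] == "C")
      }
    }, logical(1))
    # amide carbonyl: C bonded to exactly {terminal O, N, c2}
    is_c1 <- vapply(hv, function(j) {
      el[j] == "C" && {
        hj <- .heavy_neighbors(bonds, j)
        length(hj) == 3 && c2 %in% hj &&
          any(el[hj] == "N") &&
          any(el[hj] == "O" & vapply(hj, function(k) {
            el[k] == "O" && length(.heavy_neighbors(bonds, k)) == 1
          }, logical(1)))
      }
    }, logical(1))
    if (sum(is_cf3) != 1 || sum(is_o2) != 1 || sum(is_c1) != 1) next
    c3 <- hv[is_cf3]; o2 <- hv[is_o2]; c1 <- hv[is_c1]
    c5 <- setdiff(hv, c(c3, o2, c1))
    if (length(c5) != 1 || el[c5] != "C") next
    ortho <- .six_carbocycle_neighbors(bonds, c5)
    if (is.null(ortho)) next
    h1 <- .heavy_neighbors(bonds, c1)
    o1 <- h1[el[h1] == "O" & vapply(h1, function(k) length(.heavy_neighbors(bonds, k)) == 1, logical(1))]
    nn <- h1[el[h1] == "N"][1]
    c4 <- setdiff(.heavy_neighbors(bonds, o2), c2)[1]
    f_all <- .heavy_neighbors(bonds, c3)
    f_all <- f_all[el[f_all] == "F"]
    rm <- list(C1 = c1, O1 = o1[1], N = nn, C2 = c2, C3 = c3,
               F_all = f_all, O2 = o2, C4 = c4, C5 = c5,
               ortho_pair = ortho, C1p = NA_integer_, X1pp = NA_integer_,
               H1p = NA_integer_)
    class(rm) <- "mtpa_roles"
    maps[[length(maps) + 1]] <- rm
  }
  maps
}

#' Lateralize the N-substituents into synperiplanar and antiperiplanar sides
#'
#' Among the substituents of the amide nitrogen other than the carbonyl
#' carbon, the one whose torsion X-N-C1-O1 has absolute value at most 90
#' degrees is the synperiplanar substituent R^sp (its alpha atom becomes
#' C1'); the other is the antiperiplanar R^ap (alpha atom X1''). When R^ap
#' is a hydrogen, `X1pp` stays `NA` (the survey's null marker). Torsions
#' within 10 degrees of the 90-degree boundary trigger a warning. The methine
#' hydrogen H1' is filled in when C1' carries exactly one hydrogen; for a
#' heavy-atom-only methine (three heavy neighbors, no H) an idealized
#' position is inferred and flagged.
#'
#' @param structure a `crystal_structure`.
#' @param bonds a `bond_graph`.
#' @param rolemap an `mtpa_roles` from [find_mtpa_moieties()].
#' @return the role map with `C1p`, `X1pp`, `H1p` set, plus `rap_is_H`,
#'   `n_amide_h` (hydrogens on N: 1 = secondary amide, 0 = tertiary) and
#'   `h1p_inferred` (list element `H1p_xyz` holds the inferred position).
#' @export
assign_sp_ap <- function(structure, bonds, rolemap) {
  xyz <- cartesian_coordinates(structure)
  el <- bonds$elements
  subs <- setdiff(bonded_neighbors(bonds, rolemap$N), rolemap$C1)
  if (length(subs) < 1 || length(subs) > 2) {
    stop("amide N must carry one or two substituents besides C1 (found ",
         length(subs), ")")
  }
  tors <- vapply(subs, function(s) {
    torsion_angle(xyz[s, ], xyz[rolemap$N, ], xyz[rolemap$C1, ], xyz[rolemap$O1, ],
                  labels = c(structure$atoms$label[s], "N", "C1", "O1"))
  }, numeric(1))
  near <- abs(abs(tors) - 90) <= 10
  if (any(near)) {
    warning("sp/ap lateralization near the 90-degree boundary: torsion(s) ",
            paste(sprintf("%.1f", tors[near]), collapse = ", "), " degrees")
  }
  sp_side <- abs(tors) <= 90
  if (length(subs) == 2 && sum(sp_side) != 1) {
    stop("ambiguous sp/ap assignment (strongly pyramidal N): torsions ",
         paste(sprintf("%.1f", tors), collapse = ", "), " degrees")
  }
  if (length(subs) == 1) {
    # no second substituent at all (deprotonated N); treat lone side by rule
    sp <- if (sp_side[1]) subs[1] else NA_integer_
    ap <- if (!sp_side[1]) subs[1] else NA_integer_
  } else {
    sp <- subs[sp_side]
    ap <- subs[!sp_side]
  }
  rolemap$C1p <- sp
  rolemap$rap_is_H <- !is.na(ap) && el[ap] == "H"
  rolemap$X1pp <- if (is.na(ap) || el[ap] == "H") NA_integer_ else ap
  rolemap$n_amide_h <- sum(el[subs] == "H")

  rolemap$H1p <- NA_integer_
  rolemap$h1p_inferred <- FALSE
  rolemap$H1p_xyz <- NULL
  if (!is.na(sp) && el[sp] == "C") {
    hs <- setdiff(bonded_neighbors(bonds, sp), rolemap$N)
    hs_h <- hs[el[hs] == "H"]
    hs_heavy <- hs[el[hs] != "H"]
    if (length(hs_h) == 1) {
      rolemap$H1p <- hs_h
    } else if (length(hs_h) == 0 && length(hs_heavy) == 2 &&
               is.null(.six_carbocycle_neighbors(bonds, sp))) {
      # aromatic alpha carbons carry no methine H; only sp3 methines qualify
      # methine H present chemically but not located (heavy-atom-only model):
      # idealized position along the negative sum of the three heavy-neighbor
      # unit vectors at 1.09 A, flagged as inferred
      heavy3 <- c(rolemap$N, hs_heavy)
      u <- sapply(heavy3, function(j) {
        v <- xyz[j, ] - xyz[sp, ]
        v / sqrt(sum(v^2))
      })
      dir <- -rowSums(u)
      dir <- dir / sqrt(sum(dir^2))
      rolemap$H1p_xyz <- xyz[sp, ] + 1.09 * dir
      rolemap$h1p_inferred <- TRUE
    }
  }
  rolemap
}

#' Stereodescriptor at the MTPA quaternary carbon C2
#'
#' The four substituents of C2 are invariant by construction of the moiety
#' match, and their CIP priority order is fixed: O2 > C3(CF3) > C1(amide) >
#' C5(phenyl) (first sphere: O; C(F,F,F); C(O,O,N); C(C,C,C)). The descriptor
#' follows from the sign of the scalar triple product of the bond vectors to
#' the three highest-priority substituents: negative = R, positive = S
#' (mapping validated against a hand-built reference tetrahedron in the test
#' suite).
#'
#' @param structure a `crystal_structure`.
#' @param rolemap an `mtpa_roles`.
#' @return `"R"` or `"S"`.
#' @export
chirality_at_c2 <- function(structure, rolemap) {
  xyz <- cartesian_coordinates(structure)
  for (role in c("C2", "O2", "C3", "C1", "C5")) {
    if (is.na(rolemap[[role]])) stop("role map lacks ", role)
  }
  a <- xyz[rolemap$O2, ] - xyz[rolemap$C2, ]
  b <- xyz[rolemap$C3, ] - xyz[rolemap$C2, ]
  cc <- xyz[rolemap$C1, ] - xyz[rolemap$C2, ]
  trip <- sum(a * .cross3(b, cc))
  if (abs(trip) < 1e-9) stop("degenerate tetrahedron at C2")
  if (trip < 0) "R" else "S"
}

#' Classify an N-substituent by its alpha atom
#'
#' Hydrogen maps to `"H"`; an aliphatic alpha carbon with 0/1/2/3 heavy
#' non-nitrogen neighbors maps to methyl / primary / secondary / tertiary
#' alkyl; an aromatic alpha carbon (member of a six-carbon ring) maps to
#' `"aryl"`; any non-carbon alpha atom maps to a class keyed by its element
#' (e.g. `"nitrogen"`, `"sulfonyl"` for S).
#'
#' @param structure a `crystal_structure`.
#' @param bonds a `bond_graph`.
#' @param alpha_atom index of the alpha atom, or `NA` for an R^ap = H marker.
#' @return a substituent class string.
#' @export
substituent_class <- function(structure, bonds, alpha_atom) {
  if (is.na(alpha_atom)) return("H")
  el <- bonds$elements[alpha_atom]
  if (el == "H") return("H")
  if (el != "C") {
    return(switch(el, N = "nitrogen", S = "sulfonyl", P = "phosphorus",
                  O = "oxygen", Se = "selenium", tolower(el)))
  }
  if (!is.null(.six_carbocycle_neighbors(bonds, alpha_atom))) return("aryl")
  hv <- .heavy_neighbors(bonds, alpha_atom)
  # heavy-neighbor count excludes nitrogen (the amide linkage itself)
  hv <- hv[bonds$elements[hv] != "N"]
  switch(as.character(length(hv)),
         "0" = "methyl", "1" = "primary_alkyl",
         "2" = "secondary_alkyl", "3" = "tertiary_alkyl",
         "tertiary_alkyl")
}

# ordering rank within the H/alkyl chain; NA for special classes
.class_rank <- function(cls) {
  r <- match(cls, c("H", "methyl", "primary_alkyl", "secondary_alkyl", "tertiary_alkyl"))
  r
}

# atomic number of the alpha atom implied by a substituent class
.class_alpha_z <- function(cls) {
  z <- c(H = 1, methyl = 6, primary_alkyl = 6, secondary_alkyl = 6,
         tertiary_alkyl = 6, aryl = 6, phosphonoalkyl = 6, selenoxo = 6,
         thiocarbamoyl = 6, sulfonyl = 16, nitrogen = 7, phosphorus = 15,
         oxygen = 8, selenium = 34)
  unname(z[cls])
}

#' Classify the amide form (Z / E / indeterminate)
#'
#' The Z form has the larger (higher CIP priority) N-substituent
#' synperiplanar to the carbonyl oxygen, the E form antiperiplanar. Within
#' the H < methyl < primary < secondary < tertiary alkyl chain the order is
#' by heavy-neighbor count; special classes (aryl, heteroatom alpha atoms)
#' compare by the alpha atom's atomic number first, and are otherwise
#' indeterminate. Equal priority is indeterminate, never guessed.
#'
#' @param rsp_class,rap_class substituent classes of the sp and ap sides.
#' @return `"Z"`, `"E"` or `"indeterminate"`.
#' @export
#' @examples
#' classify_amide_form("secondary_alkyl", "primary_alkyl")  # "Z"
#' classify_amide_form("methyl", "secondary_alkyl")         # "E"
#' classify_amide_form("primary_alkyl", "primary_alkyl")    # "indeterminate"
classify_amide_form <- function(rsp_class, rap_class) {
  r1 <- .class_rank(rsp_class)
  r2 <- .class_rank(rap_class)
  if (!is.na(r1) && !is.na(r2)) {
    if (r1 > r2) return("Z")
    if (r1 < r2) return("E")
    return("indeterminate")
  }
  z1 <- .class_alpha_z(rsp_class)
  z2 <- .class_alpha_z(rap_class)
  if (is.na(z1) || is.na(z2)) return("indeterminate")
  if (z1 > z2) return("Z")
  if (z1 < z2) return("E")
  "indeterminate"
}
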