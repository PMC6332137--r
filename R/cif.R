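# Core CIF 1.1 reading/writing for small-molecule crystal structures.
# Scope is the core dictionary subset that CCDC small-molecule deposits use:
# cell parameters and the _atom_site fractional-coordinate loop. Unknown tags
# are ignored (with a message), mmCIF/PDBx and symmetry operators are not.

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Hf", "Ta", "W", "Re", "Os",
  "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")

# "Se1" / "SE" / "C12A" -> "Se" / "Se" / "C"
.element_from_symbol <- function(sym) {
  s <- sub("[^A-Za-z].*$", "", sym)
  two <- paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, 2)))
  one <- toupper(substr(s, 1, 1))
  ifelse(two %in% .known_elements, two,
         ifelse(one %in% .known_elements, one, NA_character_))
}

# parse "1.234(5)" -> value 1.234, su 0.005; plain numbers get su NA
.parse_su_number <- function(txt, line = NA) {
  txt <- gsub("−", "-", trimws(txt))  # unicode minus -> ASCII
  m <- regmatches(txt, regexec("^([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)(?:\\(([0-9]+)\\))?$", txt))[[1]]
  if (length(m) == 0) {
    stop("malformed numeric value '", txt, "'",
         if (!is.na(line)) paste0(" at line ", line) else "")
  }
  value <- as.numeric(m[2])
  su <- NA_real_
  if (m[3] != "") {
    dec <- if (grepl("\\.", m[2])) nchar(sub("^[^.]*\\.", "", sub("[eE].*$", "", m[2]))) else 0
    su <- as.numeric(m[3]) * 10^(-dec)
  }
  c(value = value, su = su)
}

#' Construct a crystal structure
#'
#' @param identifier text identifier (e.g. a CCDC number or data-block name).
#' @param atoms data frame with columns `label`, `element`, `x`, `y`, `z` and
#'   optionally `su_x`, `su_y`, `su_z`. Coordinates are fractional when a cell
#'   is given, Cartesian (angstrom) otherwise.
#' @param cell a [unit_cell()] or `NULL`.
#' @param fractional logical; whether `x`,`y`,`z` are fractional. Requires a
#'   cell when `TRUE`.
#' @return object of class `crystal_structure`.
#' @export
crystal_structure <- function(identifier, atoms, cell = NULL, fractional = !is.null(cell)) {
  if (nrow(atoms) < 1) stop("empty structure: need at least one atom")
  if (fractional && is.null(cell)) stop("fractional coordinates require a unit cell")
  if (anyDuplicated(atoms$label)) stop("atom labels must be unique within a structure")
  if (any(atoms$label == "")) stop("empty atom label")
  bad <- !(atoms$element %in% .known_elements)
  if (any(bad)) stop("unrecognized element symbol(s): ",
                     paste(unique(atoms$element[bad]), collapse = ", "))
  for (col in c("su_x", "su_y", "su_z")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  structure(list(identifier = as.character(identifier), cell = cell,
                 atoms = atoms, fractional = fractional),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("<crystal_structure> ", x$identifier, ": ", nrow(x$atoms), " atoms",
      if (!is.null(x$cell)) sprintf(", cell %.3f %.3f %.3f / %.2f %.2f %.2f",
                                    x$cell[1], x$cell[2], x$cell[3],
                                    x$cell[4], x$cell[5], x$cell[6]),
      "\n", sep = "")
  invisible(x)
}

#' Cartesian coordinates of a structure
#'
#' @param structure a `crystal_structure`.
#' @return n x 3 numeric matrix in angstrom, rownames = atom labels.
#' @export
cartesian_coordinates <- function(structure) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  if (structure$fractional) xyz <- fractional_to_cartesian(structure$cell, xyz)
  rownames(xyz) <- structure$atoms$label
  xyz
}

#' Read core CIF text
#'
#' Parses one or more `data_` blocks of a core CIF 1.1 file. Captures cell
#' parameters and the `_atom_site` loop (label, type symbol, fractional
#' coordinates); parenthesized standard uncertainties such as `0.1234(5)` are
#' split into value and su. Tags outside this subset are skipped.
#'
#' @param x path to a CIF file, or CIF text (single string or character
#'   vector of lines).
#' @return list of [crystal_structure()] objects, one per data block that
#'   contains atoms.
#' @export
read_cif <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
  lines <- sub("#.*$", "", lines)

  # tokenizer preserving quoted strings, with line numbers
  toks <- list()
  for (i in seq_along(lines)) {
    ll <- trimws(lines[i])
    if (ll == "") next
    pat <- "'[^']*'|\"[^\"]*\"|\\S+"
    for (tk in regmatches(ll, gregexpr(pat, ll))[[1]]) {
      if (grepl("^'.*'$", tk) || grepl('^".*"$', tk)) tk <- substr(tk, 2, nchar(tk) - 1)
      toks[[length(toks) + 1]] <- list(t = tk, line = i)
    }
  }

  structures <- list()
  n <- length(toks)
  i <- 1
  block <- NULL

  flush_block <- function(block) {
    if (is.null(block)) return(NULL)
    if (is.null(block$atoms)) stop("missing _atom_site loop in data block '",
                                   block$name, "'")
    cell <- NULL
    cp <- block$cell
    if (!is.null(cp) && all(c("a", "b", "c") %in% names(cp))) {
      ang <- function(k, d) if (k %in% names(cp)) cp[[k]] else d
      cell <- unit_cell(cp[["a"]], cp[["b"]], cp[["c"]],
                        ang("alpha", 90), ang("beta", 90), ang("gamma", 90))
    }
    crystal_structure(block$name, block$atoms, cell = cell,
                      fractional = !is.null(cell))
  }

  while (i <= n) {
    tk <- toks[[i]]$t
    if (grepl("^data_", tk, ignore.case = TRUE)) {
      s <- flush_block(block)
      if (!is.null(s)) structures[[length(structures) + 1]] <- s
      block <- list(name = sub("^data_", "", tk, ignore.case = TRUE),
                    cell = list(), atoms = NULL)
      i <- i + 1
    } else if (tolower(tk) == "loop_") {
      j <- i + 1
      tags <- character()
      while (j <= n && startsWith(toks[[j]]$t, "_")) {
        tags <- c(tags, tolower(toks[[j]]$t))
        j <- j + 1
      }
      vals <- list()
      while (j <= n && !startsWith(toks[[j]]$t, "_") &&
             !tolower(toks[[j]]$t) %in% "loop_" &&
             !grepl("^data_", toks[[j]]$t, ignore.case = TRUE)) {
        vals[[length(vals) + 1]] <- toks[[j]]
        j <- j + 1
      }
      if (any(grepl("^_atom_site_(label|fract_)", tags))) {
        if (length(vals) %% length(tags) != 0) {
          stop("ragged _atom_site loop near line ", toks[[i]]$line)
        }
        nr <- length(vals) / length(tags)
        col <- function(tag) {
          k <- match(tag, tags)
          if (is.na(k)) return(NULL)
          vapply(seq_len(nr), function(r) vals[[(r - 1) * length(tags) + k]]$t, "")
        }
        lab <- col("_atom_site_label")
        if (is.null(lab)) stop("_atom_site loop lacks _atom_site_label")
        sym <- col("_atom_site_type_symbol")
        if (is.null(sym)) sym <- lab
        num <- function(tag) {
          v <- col(tag)
          if (is.null(v)) stop("_atom_site loop lacks ", tag)
          ln <- vapply(seq_len(nr), function(r) toks[[i]]$line, 1L)
          t(vapply(seq_len(nr), function(r) .parse_su_number(v[r], ln[r]), c(0, 0)))
        }
        fx <- num("_atom_site_fract_x")
        fy <- num("_atom_site_fract_y")
        fz <- num("_atom_site_fract_z")
        el <- .element_from_symbol(sym)
        if (anyNA(el)) stop("unrecognized element symbol(s): ",
                            paste(unique(sym[is.na(el)]), collapse = ", "))
        block$atoms <- data.frame(
          label = lab, element = el,
          x = fx[, 1], y = fy[, 1], z = fz[, 1],
          su_x = fx[, 2], su_y = fy[, 2], su_z = fz[, 2],
          stringsAsFactors = FALSE)
      }
      i <- j
    } else if (startsWith(tk, "_")) {
      tag <- tolower(tk)
      if (i + 1 > n) break
      val <- toks[[i + 1]]$t
      key <- switch(tag,
        "_cell_length_a" = "a", "_cell_length_b" = "b", "_cell_length_c" = "c",
        "_cell_angle_alpha" = "alpha", "_cell_angle_beta" = "beta",
        "_cell_angle_gamma" = "gamma", NA_character_)
      if (!is.na(key)) {
        block$cell[[key]] <- .parse_su_number(val, toks[[i + 1]]$line)[["value"]]
      }
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  s <- flush_block(block)
  if (!is.null(s)) structures[[length(structures) + 1]] <- s
  if (length(structures) == 0) stop("no data block with atoms found")
  structures
}

.format_su_number <- function(value, su, digits = 6) {
  v <- formatC(value, format = "f", digits = digits)
  if (is.na(su)) return(v)
  paste0(v, "(", format(max(1, round(su * 10^digits)), scientific = FALSE), ")")
}

#' Write a structure as core CIF text
#'
#' Emits a single `data_` block readable by [read_cif()] and by mainstream
#' crystallographic software. Fractional coordinates are written when the
#' structure has a cell; standard uncertainties are preserved in the usual
#' parenthesized notation.
#'
#' @param structure a `crystal_structure`.
#' @param path optional file path; when given the text is also written there.
#' @return the CIF text, invisibly when `path` is given.
#' @export
write_cif <- function(structure, path = NULL) {
  st <- structure
  if (!inherits(st, "crystal_structure")) stop("not a crystal_structure")
  out <- c(paste0("data_", gsub("[[:space:]]", "_", st$identifier)))
  if (!is.null(st$cell)) {
    cl <- st$cell
    out <- c(out,
      sprintf("_cell_length_a    %.6f", cl[["a"]]),
      sprintf("_cell_length_b    %.6f", cl[["b"]]),
      sprintf("_cell_length_c    %.6f", cl[["c"]]),
      sprintf("_cell_angle_alpha %.6f", cl[["alpha"]]),
      sprintf("_cell_angle_beta  %.6f", cl[["beta"]]),
      sprintf("_cell_angle_gamma %.6f", cl[["gamma"]]))
  }
  out <- c(out, "loop_",
           "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
  at <- st$atoms
  if (!st$fractional && !is.null(st$cell)) {
    xyz <- cartesian_to_fractional(st$cell, as.matrix(at[, c("x", "y", "z")]))
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  } else if (!st$fractional) {
    stop("write_cif requires a unit cell (core CIF stores fractional coordinates)")
  }
  rows <- vapply(seq_len(nrow(at)), function(r) {
    paste(at$label[r], at$element[r],
          .format_su_number(at$x[r], at$su_x[r]),
          .format_su_number(at$y[r], at$su_y[r]),
          .format_su_number(at$z[r], at$su_z[r]))
  }, "")
  txt <- paste(c(out, rows, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
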