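# The packaged 58-moiety reference table of crystalline MTPA-amide torsion
# angles (one row per moiety; multi-arm molecules and multiple conformers in
# one lattice appear as separate rows), together with its integrity checks.

.torsion_cols <- c("theta1", "tauF", "tauSp", "tauAp", "tauH", "theta2", "tauOMe")

.amine_classes <- c("primary_amine", "secondary_amine", "aniline_derivative",
                    "benzotriazole", "phosphonate_derivative", "selone_derivative",
                    "thiocarbamide_derivative", "sulfonamide_derivative")

.substituent_classes <- c("H", "methyl", "primary_alkyl", "secondary_alkyl",
                          "tertiary_alkyl", "aryl", "nitrogen", "phosphonoalkyl",
                          "selenoxo", "thiocarbamoyl", "sulfonyl")

#' Load the reference torsion table
#'
#' Reads the tab-separated reference table of crystalline MTPA-amide dihedral
#' angles (58 moieties). Each torsion column holds the printed value with an
#' optional parenthesized standard uncertainty (e.g. `-13.1(2)`); the en dash
#' is the null marker. The parsed table carries one `<name>` and one
#' `<name>_su` column per descriptor, plus footnote flags.
#'
#' @param path path to the TSV; defaults to the packaged fixture.
#' @return data frame with 58 rows: `row_no`, `ccdc`, `chirality`,
#'   `amine_class`, `rsp_class`, `rap_class`, the seven torsion columns
#'   (`theta1`, `tauF`, `tauSp`, `tauAp`, `tauH`, `theta2`, `tauOMe`) with
#'   `_su` companions, and `flags` (comma-separated footnote letters).
#' @export
#' @examples
#' t1 <- load_table1()
#' t1[1, c("theta1", "theta1_su", "chirality", "flags")]
load_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_mtpa_amides.tsv", package = "mtpaconf")
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = "character", fill = TRUE)
  if (nrow(raw) != 58) {
    stop("fixture integrity: expected 58 rows, found ", nrow(raw))
  }
  out <- data.frame(
    row_no = as.integer(raw$row_no),
    ccdc = raw$ccdc,
    chirality = raw$chirality,
    amine_class = raw$amine_class,
    rsp_class = raw$rsp_class,
    rap_class = raw$rap_class,
    stringsAsFactors = FALSE)
  if (!all(out$chirality %in% c("R", "S"))) stop("fixture integrity: chirality must be R or S")
  if (!all(out$amine_class %in% .amine_classes)) {
    stop("fixture integrity: unknown amine class")
  }
  if (!all(c(out$rsp_class, out$rap_class) %in% .substituent_classes)) {
    stop("fixture integrity: unknown substituent class")
  }
  is_null_marker <- function(x) {
    x <- trimws(x)
    is.na(x) | x == "" | x %in% c("–", "—", "-", "--")
  }
  for (col in .torsion_cols) {
    txt <- gsub("−", "-", trimws(raw[[col]]))  # unicode minus -> hyphen
    val <- rep(NA_real_, length(txt))
    su <- rep(NA_real_, length(txt))
    keep <- !is_null_marker(txt)
    for (i in which(keep)) {
      p <- .parse_su_number(txt[i])
      val[i] <- p[["value"]]
      su[i] <- p[["su"]]
    }
    bad <- !is.na(val) & (val <= -180 | val > 180)
    if (any(bad)) {
      stop("fixture integrity: ", col, " outside (-180, 180] in row(s) ",
           paste(out$row_no[bad], collapse = ", "))
    }
    out[[col]] <- val
    out[[paste0(col, "_su")]] <- su
  }
  flags <- raw$flags
  flags[is.na(flags)] <- ""
  out$flags <- gsub("[[:space:]]", "", flags)
  fl <- strsplit(out$flags, ",", fixed = TRUE)
  if (!all(unlist(fl) %in% c("d", "e", "f", "g", "h", "i", "j", ""))) {
    stop("fixture integrity: unknown footnote flag")
  }
  d_rows <- has_flag(out, "d")
  if (!all(out$amine_class[d_rows] == "primary_amine")) {
    stop("fixture integrity: flag d implies a primary-amine row")
  }
  h_rows <- has_flag(out, "h")
  if (!all(out$rsp_class[h_rows] == "methyl")) {
    stop("fixture integrity: flag h implies rsp class methyl")
  }
  out
}

#' Test rows for a footnote flag
#'
#' @param rows a table as returned by [load_table1()].
#' @param flag single footnote letter.
#' @return logical vector.
#' @export
has_flag <- function(rows, flag) {
  vapply(strsplit(rows$flags, ",", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}
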