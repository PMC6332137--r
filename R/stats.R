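# Survey statistics: seam-aware (ap-wrapped) means and medians, windowed
# means with exclusion ledgers, 10-degree histograms aligned to zero, and the
# categorical tallies. Central statistics are plain arithmetic mean/median on
# the wrapped branch (the values cluster tightly, so circular estimators are
# unnecessary and harder to audit).

#' Shift antiperiplanar angles onto a contiguous branch
#'
#' Descriptors that cluster around +/-180 degrees straddle the seam of the
#' (-180, +180] convention. `wrap_ap` maps every positive value v to v - 360,
#' giving a contiguous branch in (-360, 0] on which ordinary means and
#' medians are meaningful; [rewrap_ap()] maps results back for reporting.
#'
#' @param values numeric angles in degrees, in (-180, +180].
#' @return the branch-shifted values.
#' @export
#' @examples
#' wrap_ap(c(175.6, -174.6))      # -184.4 -174.6
#' rewrap_ap(mean(wrap_ap(c(-170, 170))))  # 180, not 0
wrap_ap <- function(values) {
  ifelse(!is.na(values) & values > 0, values - 360, values)
}

#' @rdname wrap_ap
#' @export
rewrap_ap <- function(values) {
  ifelse(!is.na(values) & values <= -180, values + 360, values)
}

#' Per-descriptor summary statistics
#'
#' Computes the survey's statistics for one torsion descriptor: mean and
#' median over all non-null values (on the ap-wrapped branch when
#' `wrap_mode = "ap_seam"`, re-wrapped into (-180, +180] for reporting), and
#' optionally a windowed mean with the excluded rows listed by id.
#'
#' @param values numeric angles in degrees (NA = null).
#' @param window optional length-2 numeric window `c(lo, hi)`; membership is
#'   `lo < v <= hi` when `window_open_lower` is `TRUE` (the theta1
#'   convention) and `lo <= v <= hi` otherwise.
#' @param wrap_mode `"none"` or `"ap_seam"`.
#' @param ids optional row identifiers for the exclusion ledger.
#' @param window_open_lower logical; see `window`.
#' @return object of class `descriptor_stats`: `n_total`, `n_used`,
#'   `mean_all`, `median_all`, `windowed_mean`, `window`, `n_in_window`,
#'   `excluded` (ids outside the window), `wrap_mode`. Empty input yields an
#'   empty-stats marker (all NA, `n_used = 0`), not an error.
#' @export
descriptor_stats <- function(values, window = NULL,
                             wrap_mode = c("none", "ap_seam"), ids = NULL,
                             window_open_lower = TRUE) {
  wrap_mode <- match.arg(wrap_mode)
  if (is.null(ids)) ids <- seq_along(values)
  keep <- !is.na(values)
  v <- values[keep]
  vid <- ids[keep]
  out <- list(n_total = length(values), n_used = length(v),
              mean_all = NA_real_, median_all = NA_real_,
              windowed_mean = NA_real_, window = window,
              n_in_window = NA_integer_, excluded = NULL,
              wrap_mode = wrap_mode)
  class(out) <- "descriptor_stats"
  if (length(v) == 0) return(out)
  w <- if (wrap_mode == "ap_seam") wrap_ap(v) else v
  out$mean_all <- rewrap_ap(mean(w))
  out$median_all <- rewrap_ap(stats::median(w))
  if (!is.null(window)) {
    inw <- if (window_open_lower) {
      v > window[1] & v <= window[2]
    } else {
      v >= window[1] & v <= window[2]
    }
    out$n_in_window <- sum(inw)
    out$excluded <- vid[!inw]
    out$windowed_mean <- rewrap_ap(mean(w[inw]))
  }
  out
}

#' @export
print.descriptor_stats <- function(x, ...) {
  cat(sprintf("n = %d/%d  mean %.2f  median %.2f", x$n_used, x$n_total,
              x$mean_all, x$median_all))
  if (!is.null(x$window)) {
    cat(sprintf("  windowed mean %.2f (%d in [%g, %g], %d excluded)",
                x$windowed_mean, x$n_in_window, x$window[1], x$window[2],
                length(x$excluded)))
  }
  cat("\n")
  invisible(x)
}

#' Ten-degree histogram aligned to zero
#'
#' Bins are left-open/right-closed intervals (k*w, (k+1)*w] aligned to zero,
#' so a value of 0 falls in (-10, 0]. With `wrap_mode = "ap_seam"` the values
#' are branch-shifted first, so the seam-straddling cluster is contiguous.
#'
#' @param values numeric angles in degrees (NA dropped).
#' @param bin_width positive bin width in degrees (default 10).
#' @param wrap_mode `"none"` or `"ap_seam"`.
#' @return object of class `angle_histogram`: `breaks`, `counts`, `mids`,
#'   `bin_width`, `wrap_mode`. Counts always sum to the number of non-null
#'   values.
#' @export
build_histogram <- function(values, bin_width = 10,
                            wrap_mode = c("none", "ap_seam")) {
  wrap_mode <- match.arg(wrap_mode)
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a positive number")
  }
  v <- values[!is.na(values)]
  if (wrap_mode == "ap_seam") v <- wrap_ap(v)
  if (length(v) == 0) {
    out <- list(breaks = c(-bin_width, 0), counts = 0L,
                mids = -bin_width / 2, bin_width = bin_width,
                wrap_mode = wrap_mode)
    class(out) <- "angle_histogram"
    return(out)
  }
  lo <- bin_width * (ceiling(min(v) / bin_width) - 1)
  hi <- bin_width * ceiling(max(v) / bin_width)
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.integer(table(cut(v, breaks = breaks, right = TRUE)))
  out <- list(breaks = breaks, counts = counts,
              mids = breaks[-1] - bin_width / 2, bin_width = bin_width,
              wrap_mode = wrap_mode)
  class(out) <- "angle_histogram"
  out
}

#' @export
print.angle_histogram <- function(x, ...) {
  lab <- sprintf("(%g,%g]", x$breaks[-length(x$breaks)], x$breaks[-1])
  cat(paste0(lab, ": ", x$counts, collapse = "  "), "\n")
  invisible(x)
}

#' Tally amide Z/E/indeterminate forms by amide arity
#'
#' @param rows classified rows ([classify_rows()]) with `amide_form` and
#'   `arity` columns.
#' @return data frame with one row per arity present (plus an `all` row):
#'   counts `Z`, `E`, `indeterminate`.
#' @export
tally_amide_forms <- function(rows) {
  tally_one <- function(f) {
    c(Z = sum(f == "Z"), E = sum(f == "E"),
      indeterminate = sum(f == "indeterminate"))
  }
  arities <- c("secondary", "tertiary")
  res <- lapply(arities, function(a) tally_one(rows$amide_form[rows$arity == a]))
  out <- as.data.frame(do.call(rbind, c(res, list(tally_one(rows$amide_form)))))
  out$arity <- c(arities, "all")
  out[, c("arity", "Z", "E", "indeterminate")]
}

# descriptor panel configuration: window, wrap, print precision of the median
.survey_panel <- list(
  theta1 = list(window = c(-30, 0), wrap = "none", open_lower = TRUE, med_digits = 1),
  tauF   = list(window = NULL, wrap = "ap_seam", med_digits = 0),
  tauSp  = list(window = NULL, wrap = "none", med_digits = 1),
  tauAp  = list(window = NULL, wrap = "ap_seam", med_digits = 0),
  tauH   = list(window = NULL, wrap = "none", med_digits = 0),
  theta2 = list(window = c(0, 50), wrap = "none", open_lower = FALSE, med_digits = 0),
  tauOMe = list(window = c(30, 80), wrap = "none", open_lower = FALSE, med_digits = 0)
)

#' Summarize a survey of MTPA-amide moieties
#'
#' The package's survey report: per-descriptor statistics (seam-aware medians,
#' windowed means with exclusion ledgers), 10-degree histograms, amide-form
#' tallies and amine-class subtotals, computed from a table of R-normalized
#' moiety records. Windows follow the survey conventions: theta1 in
#' (-30, 0], theta2 in [0, +50], methoxy rotamer in [+30, +80]; the
#' antiperiplanar descriptors (tauF, tauAp) are branch-shifted across the
#' +/-180 seam before averaging; tauH statistics are restricted to
#' Mosher-type moieties (secondary amide, secondary-alkyl sp substituent).
#'
#' @param rows a torsion table: [load_table1()] output, [analyze_structure()]
#'   output, or any data frame with the seven torsion columns, `chirality`,
#'   `rsp_class`, `rap_class` (rows are normalized and classified on the fly
#'   when needed).
#' @param include_special_sp when `FALSE`, rows whose sp-side angle was
#'   measured to a non-carbon alpha atom (footnote-j style records) are
#'   dropped from the tauSp statistics. Default `TRUE` (all non-null values).
#' @return object of class `mtpa_survey`: list with `n_moieties`,
#'   `n_structures`, `amine_class_counts`, `stats` (per-descriptor
#'   [descriptor_stats()]), `histograms`, `amide_tally`,
#'   `tertiary_secondary_amine_tally`, `primary_amine_Z`, `mosher_rows`,
#'   `rows` (the classified table) and `panel` (the as-printed values:
#'   medians at the survey's print precision, windowed means to the nearest
#'   degree).
#' @export
#' @examples
#' sv <- mtpa_survey(load_table1())
#' print(sv)
mtpa_survey <- function(rows, include_special_sp = TRUE) {
  rows <- classify_rows(rows)
  ids <- if (!is.null(rows$row_no)) rows$row_no else seq_len(nrow(rows))

  stats_out <- list()
  histos <- list()
  for (d in names(.survey_panel)) {
    cfg <- .survey_panel[[d]]
    vals <- rows[[d]]
    use <- rep(TRUE, nrow(rows))
    if (d == "tauH") use <- rows$mosher_type
    if (d == "tauSp" && !include_special_sp) {
      # drop rows whose sp angle was measured to a non-carbon alpha atom
      use <- .class_alpha_z(rows$rsp_class) %in% c(1, 6)
    }
    v <- ifelse(use, vals, NA_real_)
    stats_out[[d]] <- descriptor_stats(
      v, window = cfg$window, wrap_mode = cfg$wrap, ids = ids,
      window_open_lower = isTRUE(cfg$open_lower))
    histos[[d]] <- build_histogram(v, bin_width = 10, wrap_mode = cfg$wrap)
  }

  tert_sec <- rows[rows$arity == "tertiary" &
                     !is.null(rows$amine_class) &
                     rows$amine_class == "secondary_amine", , drop = FALSE]
  if (is.null(rows$amine_class)) {
    tert_sec <- rows[rows$arity == "tertiary", , drop = FALSE]
  }
  tst <- c(Z = sum(tert_sec$amide_form == "Z"),
           E = sum(tert_sec$amide_form == "E"),
           indeterminate = sum(tert_sec$amide_form == "indeterminate"))

  prim <- if (!is.null(rows$amine_class)) {
    rows[rows$amine_class == "primary_amine", , drop = FALSE]
  } else {
    rows[rows$arity == "secondary", , drop = FALSE]
  }

  panel <- list(
    theta1_median = round(stats_out$theta1$median_all, 1),
    theta1_windowed_mean = round(stats_out$theta1$windowed_mean),
    theta1_n_in_window = stats_out$theta1$n_in_window,
    tauF_median = round(stats_out$tauF$median_all),
    tauSp_mean = round(stats_out$tauSp$mean_all),
    tauSp_median = round(stats_out$tauSp$median_all, 1),
    tauAp_median = round(stats_out$tauAp$median_all),
    tauH_mean = round(stats_out$tauH$mean_all),
    tauH_median = round(stats_out$tauH$median_all),
    theta2_windowed_mean = round(stats_out$theta2$windowed_mean),
    theta2_n_in_window = stats_out$theta2$n_in_window,
    theta2_median = round(stats_out$theta2$median_all),
    tauOMe_windowed_mean = round(stats_out$tauOMe$windowed_mean),
    tauOMe_n_in_window = stats_out$tauOMe$n_in_window,
    tauOMe_median = round(stats_out$tauOMe$median_all))

  out <- list(
    n_moieties = nrow(rows),
    n_structures = if (!is.null(rows$ccdc)) length(unique(rows$ccdc)) else NA_integer_,
    amine_class_counts = if (!is.null(rows$amine_class)) table(rows$amine_class) else NULL,
    stats = stats_out,
    histograms = histos,
    amide_tally = tally_amide_forms(rows),
    tertiary_secondary_amine_tally = tst,
    primary_amine_Z = sum(prim$amide_form == "Z"),
    n_primary_amine = nrow(prim),
    mosher_rows = ids[rows$mosher_type],
    panel = panel,
    rows = rows)
  class(out) <- "mtpa_survey"
  out
}

#' @export
print.mtpa_survey <- function(x, ...) {
  cat("MTPA-amide conformational survey\n")
  cat(sprintf("  %d moieties from %s structures\n", x$n_moieties,
              ifelse(is.na(x$n_structures), "?", x$n_structures)))
  if (!is.null(x$amine_class_counts)) {
    cc <- x$amine_class_counts
    cat("  amine classes: ",
        paste(names(cc), as.integer(cc), sep = "=", collapse = ", "), "\n")
  }
  p <- x$panel
  w1 <- x$stats$theta1
  cat(sprintf("  theta1 (O1-C1-C2-C3): median %+.1f; windowed mean %+d with %d/%d in (-30, 0]\n",
              p$theta1_median, p$theta1_windowed_mean, p$theta1_n_in_window, w1$n_used))
  cat(sprintf("  C1-C2-C3-F3: ap-wrapped median %+d (staggered CF3)\n", p$tauF_median))
  cat(sprintf("  C1'-N-C1-O1: mean %+d, median %+.1f (amide planarity)\n",
              p$tauSp_mean, p$tauSp_median))
  cat(sprintf("  X1''-N-C1-O1: ap-wrapped median %+d over %d non-null rows\n",
              p$tauAp_median, x$stats$tauAp$n_used))
  cat(sprintf("  H1'-C1'-N-C1 (Mosher-type, n=%d): mean %+d, median %+d\n",
              x$stats$tauH$n_used, p$tauH_mean, p$tauH_median))
  cat(sprintf("  theta2 (O2-C2-C5-C10): windowed mean %+d with %d/%d in [0, +50]; median %+d\n",
              p$theta2_windowed_mean, p$theta2_n_in_window, x$stats$theta2$n_used,
              p$theta2_median))
  cat(sprintf("  C1-C2-O2-C4: windowed mean %+d with %d/%d in [+30, +80]; median %+d\n",
              p$tauOMe_windowed_mean, p$tauOMe_n_in_window, x$stats$tauOMe$n_used,
              p$tauOMe_median))
  tst <- x$tertiary_secondary_amine_tally
  cat(sprintf("  amide forms, tertiary (secondary amines): Z:E = %d:%d with %d indeterminate\n",
              tst[["Z"]], tst[["E"]], tst[["indeterminate"]]))
  cat(sprintf("  amide forms, primary-amine rows: %d/%d Z\n",
              x$primary_amine_Z, x$n_primary_amine))
  invisible(x)
}

#' Histogram panel of a survey
#'
#' Draws the per-descriptor 10-degree histograms as bar plots (bins are
#' left-open/right-closed, aligned to zero).
#'
#' @param x an `mtpa_survey`.
#' @param descriptors which descriptors to draw.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, `x`.
#' @export
plot.mtpa_survey <- function(x, descriptors = names(x$histograms), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(descriptors)))
  on.exit(graphics::par(old))
  for (d in descriptors) {
    h <- x$histograms[[d]]
    graphics::barplot(h$counts, names.arg = sprintf("%g", h$breaks[-1]),
                      main = d, xlab = "torsion (deg, right bin edge)",
                      ylab = "count", ...)
  }
  invisible(x)
}

#' Serialize a survey report to JSON
#'
#' @param survey an `mtpa_survey`.
#' @param path optional output file.
#' @param pretty pretty-print flag.
#' @return JSON string (invisibly when `path` given).
#' @export
survey_json <- function(survey, path = NULL, pretty = TRUE) {
  strip <- function(s) {
    s$rows <- NULL
    s$histograms <- lapply(s$histograms, unclass)
    s$stats <- lapply(s$stats, unclass)
    s$amine_class_counts <- as.list(s$amine_class_counts)
    unclass(s)
  }
  js <- jsonlite::toJSON(strip(survey), auto_unbox = TRUE, digits = NA,
                         pretty = pretty, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
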