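#' Round half away from zero
#'
#' The reporting convention of the assessment: ties round away from zero
#' (87.5% prints as 88%), unlike R's banker's rounding. Computation is at
#' full precision throughout the engine; this is display-layer only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (>= 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(87.5, 0)  # 88
#' round(87.5)               # 88 by accident; round(0.5) is 0
#' round_half_away(0.5, 0)   # 1
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by one ulp so that values which are exact ties in decimal but sit
  # just below .5 in binary (e.g. 791.145 stored as 791.14499...) still
  # round up
  sign(x) * floor(abs(x) * scale + 0.5 + .Machine$double.eps * abs(x) *
                    scale) / scale
}

#' Reporting options
#'
#' @param decimals_ewi Decimal places for EWI and HI values (default 2, the
#'   assessment's convention).
#' @param pct_as_integer Render %TWI as whole percentages (default TRUE).
#' @param rounding Rounding mode; only `"half_away_from_zero"` is defined.
#' @param output_format One of `"csv"`, `"json"`, `"text"`.
#' @return A list of validated options for [round_report()] and
#'   [render_risk_report()].
#' @export
report_options <- function(decimals_ewi = 2, pct_as_integer = TRUE,
                           rounding = "half_away_from_zero",
                           output_format = c("csv", "json", "text")) {
  if (decimals_ewi < 0) stop("decimals_ewi must be >= 0", call. = FALSE)
  rounding <- match.arg(rounding, "half_away_from_zero")
  list(decimals_ewi = decimals_ewi, pct_as_integer = pct_as_integer,
       rounding = rounding, output_format = match.arg(output_format))
}

#' Format a value for the risk report
#'
#' EWIs and hazard indices print with two decimals; %TWI prints as an
#' integer percentage; ties round half away from zero. A positive value
#' that formats to `"0.00"` is kept as such: it means below display
#' precision, never absent.
#'
#' @param value Non-negative numeric vector (full-precision engine values).
#' @param kind `"ewi"`, `"pct"` or `"hi"`.
#' @param options Options from [report_options()].
#' @return Character vector of display strings.
#' @examples
#' round_report(3.85 / 4.4 * 100, "pct")  # "88%"
#' round_report(7.9114, "hi")             # "7.91"
#' round_report(0.004, "ewi")             # "0.00"
#' @export
round_report <- function(value, kind = c("ewi", "pct", "hi"),
                         options = report_options()) {
  kind <- match.arg(kind)
  if (any(value < 0)) stop("report values must be >= 0", call. = FALSE)
  if (kind == "pct") {
    digits <- if (options$pct_as_integer) 0 else options$decimals_ewi
    paste0(formatC(round_half_away(value, digits), format = "f",
                   digits = digits), "%")
  } else {
    formatC(round_half_away(value, options$decimals_ewi), format = "f",
            digits = options$decimals_ewi)
  }
}

#' Render a per-category report table
#'
#' One wide table per food category in the layout of the assessment's
#' printed tables: a column per compound — range-valued compounds get
#' `(Min)`/`(Max)` column pairs — plus cumulative min/max columns, and per
#' group one `PEQ-EWI` row and one `%TWI` row (plus `CB-%TWI` when the
#' assessment includes the CB mode).
#'
#' @param assessment A `pfas_risk` object from [build_exposure_table()]
#'   computed with both scenarios.
#' @param food_category One of [food_categories()].
#' @param options Options from [report_options()].
#' @return A data frame of display strings.
#' @export
render_category_table <- function(assessment, food_category,
                                  options = report_options()) {
  stopifnot(inherits(assessment, "pfas_risk"))
  cells <- assessment$cells
  cells <- cells[cells$food_category == food_category, , drop = FALSE]
  summ <- assessment$category_summary
  summ <- summ[summ$food_category == food_category, , drop = FALSE]
  groups <- unique(summ$group)
  peq <- cells[cells$mode == "PEQ", , drop = FALSE]
  compounds <- sort(unique(cells$compound))
  ranged <- vapply(compounds, function(cp) {
    e <- peq$ewi[peq$compound == cp]
    length(e) > 0 && diff(range(e)) > 0
  }, logical(1))

  col_names <- unlist(lapply(compounds, function(cp) {
    if (isTRUE(ranged[[cp]])) paste0(cp, c(" (Min)", " (Max)")) else cp
  }))
  header <- c("group", "row", col_names, "Cumulative EWI (Min)",
              "Cumulative EWI (Max)")

  fetch <- function(df, cp, sc, col) {
    v <- df[df$compound == cp & df$scenario == sc, ][[col]]
    if (length(v) == 0) NA_real_ else v
  }
  rows <- list()
  for (g in groups) {
    pg <- peq[peq$group == g, , drop = FALSE]
    sg <- summ[summ$group == g & summ$mode == "PEQ", , drop = FALSE]
    for (row_kind in c("PEQ-EWI", "%TWI")) {
      vals <- unlist(lapply(compounds, function(cp) {
        scs <- if (isTRUE(ranged[[cp]])) c("min", "max") else "min"
        vapply(scs, function(sc) {
          col <- if (row_kind == "PEQ-EWI") "ewi" else "pct_twi"
          v <- fetch(pg, cp, sc, col)
          if (is.na(v)) "" else
            round_report(v, if (row_kind == "PEQ-EWI") "ewi" else "pct",
                         options)
        }, character(1))
      }))
      kind <- if (row_kind == "PEQ-EWI") "ewi" else "pct"
      col <- if (row_kind == "PEQ-EWI") "cumulative_ewi" else "pct_twi"
      cum <- vapply(c("min", "max"), function(sc)
        round_report(sg[[col]][sg$scenario == sc], kind, options),
        character(1))
      rows[[length(rows) + 1]] <- c(g, row_kind, vals, cum)
    }
    if ("CB" %in% cells$mode) {
      cg <- cells[cells$mode == "CB" & cells$group == g &
                    cells$scenario == cells$scenario[1], , drop = FALSE]
      sgc <- summ[summ$group == g & summ$mode == "CB" &
                    summ$scenario == summ$scenario[1], , drop = FALSE]
      vals <- unlist(lapply(compounds, function(cp) {
        n_cols <- if (isTRUE(ranged[[cp]])) 2 else 1
        v <- cg$pct_twi[cg$compound == cp]
        first <- if (length(v) == 0) "" else round_report(v, "pct", options)
        c(first, rep("", n_cols - 1))
      }))
      cum <- c(round_report(sgc$pct_twi, "pct", options), "")
      rows[[length(rows) + 1]] <- c(g, "CB-%TWI", vals, cum)
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- header
  out
}

#' Write the full risk report
#'
#' Writes one CSV per food category ([render_category_table()] layout), a
#' totals CSV with total EWIs and hazard indices per group, and a JSON
#' mirror of the full-precision summaries. Output is deterministic: the
#' same assessment and options produce byte-identical files.
#'
#' @param assessment A `pfas_risk` object computed with both scenarios.
#' @param dir Output directory (created if needed).
#' @param options Options from [report_options()].
#' @return Invisibly, the paths written.
#' @export
render_risk_report <- function(assessment, dir, options = report_options()) {
  stopifnot(inherits(assessment, "pfas_risk"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (cat in intersect(food_categories(),
                        unique(assessment$category_summary$food_category))) {
    tbl <- render_category_table(assessment, cat, options)
    p <- file.path(dir, paste0("ewi_", cat, ".csv"))
    write.csv(tbl, p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }

  totals <- assessment$totals
  disp <- data.frame(
    group = totals$group, mode = totals$mode, scenario = totals$scenario,
    total_ewi = round_report(totals$total_ewi, "ewi", options),
    pct_twi = round_report(totals$pct_twi, "pct", options),
    hazard_index = round_report(totals$hazard_index, "hi", options),
    stringsAsFactors = FALSE
  )
  p <- file.path(dir, "totals.csv")
  write.csv(disp, p, row.names = FALSE, quote = TRUE)
  paths <- c(paths, p)

  p <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(twi = assessment$twi, bound = assessment$bound,
         category_summary = assessment$category_summary,
         totals = totals),
    p, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
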