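#' Reference tables from the published European assessment
#'
#' The package ships verbatim transcriptions of the printed tables of the
#' published European cumulative PFAS dietary assessment it reimplements:
#' the consumption grid, the RPF grid, the per-compound PEQ weekly intakes
#' for each food category, the per-category cumulative intakes, and the
#' group totals with hazard indices. They serve as frozen fixtures for
#' regression and acceptance testing and are never regenerated.
#'
#' Available identifiers (aliases in parentheses):
#' * `"consumption"` (`"T1"`) — mean consumption g/day per category x group
#' * `"rpf"` (`"T2"`) — RPF grid (with the PFPeA hepatic value 0.03; see
#'   [default_rpf_table()])
#' * `"milk_dairy"`, `"meat"`, `"eggs"`, `"fish_seafood"` (`"T3"`..`"T6"`)
#'   — per-compound PEQ-EWIs, min/max scenario, per group
#' * `"cumulative"` — per-category cumulative PEQ-EWIs (min/max)
#' * `"totals"` (`"T7"`) — total PEQ-EWIs, PEQ hazard indices and the
#'   concentration-based hazard index per group
#' * `"totals_by_compound"` — per-compound total PEQ-EWIs across categories
#'
#' @param id One of the identifiers above.
#' @return A tibble of the requested reference values (ng/kg bw per week for
#'   intakes; g/day for consumption; dimensionless for RPFs and HIs).
#' @examples
#' reference_table("consumption")
#' reference_table("T7")
#' @seealso [validate_reference_tables()] for the fixture self-check.
#' @export
reference_table <- function(id) {
  aliases <- c(T1 = "consumption", T2 = "rpf", T3 = "milk_dairy",
               T4 = "meat", T5 = "eggs", T6 = "fish_seafood", T7 = "totals")
  if (id %in% names(aliases)) id <- aliases[[id]]
  files <- c(consumption = "consumption.csv", rpf = "rpf.csv",
             milk_dairy = "ewi_milk_dairy.csv", meat = "ewi_meat.csv",
             eggs = "ewi_eggs.csv", fish_seafood = "ewi_fish_seafood.csv",
             cumulative = "cumulative.csv", totals = "totals.csv",
             totals_by_compound = "totals_by_compound.csv")
  if (!id %in% names(files)) {
    stop("unknown reference table: ", id, " (expected one of ",
         paste(c(names(files), names(aliases)), collapse = ", "), ")",
         call. = FALSE)
  }
  path <- reference_path(files[[id]])
  tbl <- switch(id,
    consumption = read_consumption_table(path),
    rpf = read_rpf_table(path),
    tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  )
  check_reference_shape(id, tbl)
  tbl
}

check_reference_shape <- function(id, tbl) {
  expected_rows <- c(consumption = 16L, rpf = 19L, milk_dairy = 32L,
                     meat = 64L, eggs = 28L, fish_seafood = 56L,
                     cumulative = 16L, totals = 4L,
                     totals_by_compound = 64L)
  if (nrow(tbl) != expected_rows[[id]] || anyNA(tbl)) {
    stop("reference table ", id, " is corrupted (unexpected shape)",
         call. = FALSE)
  }
  if ("group" %in% names(tbl)) {
    check_levels(tbl$group, population_groups(), "group")
  }
  if ("ewi_min" %in% names(tbl) &&
      any(tbl$ewi_min > tbl$ewi_max + 1e-12)) {
    stop("reference table ", id, " is corrupted (min > max)", call. = FALSE)
  }
  invisible(tbl)
}

#' Self-check of the shipped reference tables
#'
#' Verifies the internal identities that the transcribed tables must
#' satisfy:
#' * per-category cumulative intakes sum exactly (to printed precision) to
#'   the group totals for both scenarios;
#' * the toddler milk/dairy per-compound row sums exactly to its printed
#'   cumulative; the other rows agree within `tol` (their components and
#'   cumulatives were rounded independently from full precision);
#' * per-compound totals match the across-category compound sums within
#'   `tol`;
#' * the printed hazard indices equal the totals divided by the TWI of 4.4,
#'   rounded half-away-from-zero to two decimals;
#' * the consumption and RPF grids are complete.
#'
#' @param tol Tolerance (ng/kg bw per week) for identities affected by
#'   independent component rounding; default 0.02.
#' @return Invisibly `TRUE`; stops with a fixture-corruption error
#'   otherwise.
#' @export
validate_reference_tables <- function(tol = 0.02) {
  cons <- reference_table("consumption")
  if (nrow(unique(cons[, c("food_category", "group")])) != 16) {
    stop("consumption grid incomplete", call. = FALSE)
  }
  reference_table("rpf")

  cum <- reference_table("cumulative")
  totals <- reference_table("totals")
  for (g in population_groups()) {
    cg <- cum[cum$group == g, ]
    tg <- totals[totals$group == g, ]
    if (abs(sum(cg$cumulative_min) - tg$total_min) > 1e-9 ||
        abs(sum(cg$cumulative_max) - tg$total_max) > 1e-9) {
      stop("cumulative/total identity fails for ", g, call. = FALSE)
    }
    hi_min <- round_half_away(hazard_index(tg$total_min), 2)
    hi_max <- round_half_away(hazard_index(tg$total_max), 2)
    if (hi_min != tg$peq_hi_min || hi_max != tg$peq_hi_max) {
      stop("hazard-index identity fails for ", g, call. = FALSE)
    }
  }

  for (cat in food_categories()) {
    ewi <- reference_table(cat)
    cc <- cum[cum$food_category == cat, ]
    for (g in population_groups()) {
      eg <- ewi[ewi$group == g, ]
      band <- if (cat == "milk_dairy" && g == "toddlers") 1e-9 else tol
      if (abs(sum(eg$ewi_min) - cc$cumulative_min[cc$group == g]) > band + 1e-9 ||
          abs(sum(eg$ewi_max) - cc$cumulative_max[cc$group == g]) > band + 1e-9) {
        stop("row-sum identity fails for ", cat, " / ", g, call. = FALSE)
      }
    }
  }

  by_comp <- reference_table("totals_by_compound")
  per_cat <- dplyr::bind_rows(lapply(food_categories(), reference_table))
  sums <- dplyr::summarise(
    dplyr::group_by(per_cat, .data$group, .data$compound),
    min_sum = sum(.data$ewi_min), max_sum = sum(.data$ewi_max),
    .groups = "drop")
  joined <- dplyr::inner_join(by_comp, sums, by = c("group", "compound"))
  if (any(abs(joined$ewi_min - joined$min_sum) > tol + 1e-9) ||
      any(abs(joined$ewi_max - joined$max_sum) > tol + 1e-9)) {
    stop("per-compound total identity fails", call. = FALSE)
  }
  invisible(TRUE)
}
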