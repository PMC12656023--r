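#' Lower/upper-bound mean of left-censored sample records
#'
#' Substitution estimator for occurrence data dominated by non-detects:
#' under the lower bound (LB) censored records contribute 0, under the upper
#' bound (UB) they contribute their quantification limit (LOQ preferred,
#' LOD when no LOQ is reported). Quantified records contribute their
#' measured value in both bounds. The result is the arithmetic mean.
#'
#' @param samples Data frame of sample records for one compound and food
#'   category: columns `censored` (logical), `value` (ng/kg, quantified
#'   records), `lod`, `loq` (ng/kg, censored records); see
#'   [read_sample_records()].
#' @param bound `"LB"` or `"UB"`.
#' @return Mean concentration in ng/kg food.
#' @examples
#' smp <- tibble::tibble(
#'   compound = "PFOS", food_category = "fish_seafood",
#'   censored = c(TRUE, FALSE), value = c(NA, 100), lod = c(10, NA),
#'   loq = c(NA, NA)
#' )
#' bound_mean(smp, "LB")  # 50
#' bound_mean(smp, "UB")  # 55
#' @export
bound_mean <- function(samples, bound = c("LB", "UB")) {
  bound <- match.arg(bound)
  samples <- validate_sample_records(samples)
  if (nrow(samples) == 0) {
    stop("bound_mean needs at least one sample record", call. = FALSE)
  }
  for (col in c("compound", "food_category")) {
    if (length(unique(samples[[col]])) > 1) {
      stop("samples mix more than one ", col, call. = FALSE)
    }
  }
  contrib <- ifelse(samples$censored, 0, samples$value)
  if (bound == "UB") {
    limit <- ifelse(is.na(samples$loq), samples$lod, samples$loq)
    if (any(samples$censored & is.na(limit))) {
      stop("UB substitution needs lod or loq for every censored record",
           call. = FALSE)
    }
    contrib <- ifelse(samples$censored, limit, samples$value)
  }
  mean(contrib)
}

#' Survey-weighted mean consumption
#'
#' European mean consumption of a food category for a consumer group,
#' computed as the weighted mean of individual Member State survey means
#' (weights are typically subject counts).
#'
#' @param surveys Data frame with columns `mean_consumption` (g/day) and
#'   `weight` (> 0) for a single food category and group; see
#'   [read_survey_table()].
#' @return Weighted mean consumption in g/day.
#' @examples
#' srv <- tibble::tibble(
#'   survey_id = c("a", "b"), food_category = "meat", group = "adults",
#'   mean_consumption = c(10, 30), weight = c(100, 300)
#' )
#' weighted_mean_consumption(srv)  # 25
#' @export
weighted_mean_consumption <- function(surveys) {
  surveys <- validate_survey_table(surveys)
  if (nrow(surveys) == 0) {
    stop("weighted_mean_consumption needs at least one survey", call. = FALSE)
  }
  for (col in c("food_category", "group")) {
    if (length(unique(surveys[[col]])) > 1) {
      stop("surveys mix more than one ", col, call. = FALSE)
    }
  }
  total_w <- sum(surveys$weight)
  if (total_w <= 0) stop("total survey weight must be > 0", call. = FALSE)
  sum(surveys$weight * surveys$mean_consumption) / total_w
}

#' Build the full exposure table and risk summaries
#'
#' The assessment engine: combines per-compound occurrence means with mean
#' consumption and standard body weights into one exposure cell per compound
#' x food category x consumer group x mode x scenario, then cumulates per
#' category, totals across categories and characterises risk against the
#' TWI.
#'
#' Modes: `"PEQ"` weights each concentration by its RPF (resolved coherently
#' under the min or max scenario for read-across compounds); `"CB"` is the
#' unweighted concentration-based comparator, for which the scenario has no
#' effect. All arithmetic is at full floating precision; rounding is applied
#' only when rendering ([round_report()]).
#'
#' @param occurrence Occurrence tibble (`compound`, `food_category`,
#'   `mean_lb`, optional `mean_ub`); see [read_occurrence_table()].
#' @param rpf RPF table; defaults to [default_rpf_table()].
#' @param consumption Consumption tibble; defaults to
#'   [default_consumption_table()].
#' @param body_weights Named numeric vector of body weights in kg; defaults
#'   to [default_body_weights()].
#' @param groups Consumer groups to assess; defaults to every group present
#'   in `consumption`.
#' @param mode Character vector, subset of `c("PEQ", "CB")`.
#' @param scenario Character vector, subset of `c("min", "max")`.
#' @param bound Which occurrence bound feeds the engine: `"LB"` (default,
#'   the realistic estimate) or `"UB"` (requires `mean_ub`).
#' @param twi Tolerable weekly intake, ng/kg bw per week.
#' @param skip_compounds Compounds in `occurrence` to drop (with a warning)
#'   instead of failing when they have no RPF assignment.
#' @return A `pfas_risk` object: list with tibbles `cells` (per-compound
#'   EWIs and %TWI), `category_summary` (cumulative EWI and %TWI per
#'   category), `totals` (total EWI and hazard index per group), plus the
#'   `twi` and `bound` used.
#' @examples
#' occ <- tibble::tibble(compound = "PFOS", food_category = "fish_seafood",
#'                       mean_lb = 1507.8125, mean_ub = NA_real_)
#' risk <- build_exposure_table(occ, groups = "adults")
#' risk$totals
#' @export
build_exposure_table <- function(occurrence,
                                 rpf = default_rpf_table(),
                                 consumption = default_consumption_table(),
                                 body_weights = default_body_weights(),
                                 groups = NULL,
                                 mode = c("PEQ", "CB"),
                                 scenario = c("min", "max"),
                                 bound = c("LB", "UB"),
                                 twi = twi_default(),
                                 skip_compounds = character()) {
  mode <- match.arg(mode, several.ok = TRUE)
  scenario <- match.arg(scenario, several.ok = TRUE)
  bound <- match.arg(bound)
  occurrence <- validate_occurrence_table(occurrence)
  rpf <- validate_rpf_table(rpf)
  consumption <- validate_consumption_table(consumption)
  if (is.null(groups)) groups <- unique(consumption$group)
  check_levels(groups, population_groups(), "group")
  missing_bw <- setdiff(groups, names(body_weights))
  if (length(missing_bw) > 0) {
    stop("no body weight for group(s): ",
         paste(missing_bw, collapse = ", "), call. = FALSE)
  }
  if (any(body_weights[groups] <= 0)) {
    stop("body weights must be > 0", call. = FALSE)
  }

  unmatched <- setdiff(occurrence$compound, c(rpf$compound, skip_compounds))
  if (length(unmatched) > 0) {
    stop("occurrence compound(s) without RPF assignment: ",
         paste(unmatched, collapse = ", "),
         "; add them to the RPF table or to `skip_compounds`",
         call. = FALSE)
  }
  skipped <- intersect(occurrence$compound, skip_compounds)
  if (length(skipped) > 0) {
    warning("dropping compound(s) without RPF: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
    occurrence <- occurrence[!occurrence$compound %in% skip_compounds, ,
                             drop = FALSE]
  }

  occurrence$conc <- if (bound == "LB") occurrence$mean_lb else occurrence$mean_ub
  if (bound == "UB" && anyNA(occurrence$conc)) {
    stop("UB assessment requires mean_ub for every occurrence record",
         call. = FALSE)
  }

  empty_cats <- setdiff(unique(consumption$food_category),
                        unique(occurrence$food_category))
  if (length(empty_cats) > 0 && nrow(occurrence) > 0) {
    warning("no occurrence records for categor",
            if (length(empty_cats) == 1) "y: " else "ies: ",
            paste(empty_cats, collapse = ", "),
            "; cumulative EWI set to 0", call. = FALSE)
  }

  grid <- tidyr::expand_grid(group = groups, mode = mode,
                             scenario = scenario)
  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid$group[i]
    m <- grid$mode[i]
    s <- grid$scenario[i]
    cons_g <- consumption[consumption$group == g, ,
                          drop = FALSE]
    cell <- dplyr::inner_join(occurrence, cons_g, by = "food_category")
    if (nrow(cell) == 0) {
      cells[[i]] <- NULL
      next
    }
    r <- if (m == "PEQ") resolve_rpf(cell$compound, s, rpf) else
      rep(1, nrow(cell))
    ewi <- weekly_intake_term(cell$conc, r, cell$mean_consumption,
                              body_weights[[g]])
    cells[[i]] <- tibble::tibble(
      compound = cell$compound,
      food_category = cell$food_category,
      group = g, mode = m, scenario = s,
      rpf = r, ewi = ewi, pct_twi = pct_twi(ewi, twi)
    )
  }
  cells <- dplyr::bind_rows(cells)
  if (nrow(cells) == 0) {
    cells <- tibble::tibble(compound = character(),
                            food_category = character(),
                            group = character(), mode = character(),
                            scenario = character(), rpf = numeric(),
                            ewi = numeric(), pct_twi = numeric())
  }

  # per-category cumulatives on the full group x mode x scenario x category
  # grid: categories with no occurrence contribute 0
  full <- tidyr::expand_grid(group = groups, mode = mode,
                             scenario = scenario,
                             food_category = unique(consumption$food_category))
  summed <- dplyr::summarise(
    dplyr::group_by(cells, .data$group, .data$mode, .data$scenario,
                    .data$food_category),
    cumulative_ewi = sum(.data$ewi), .groups = "drop")
  category_summary <- dplyr::left_join(
    full, summed, by = c("group", "mode", "scenario", "food_category"))
  category_summary$cumulative_ewi[is.na(category_summary$cumulative_ewi)] <- 0
  category_summary$pct_twi <- pct_twi(category_summary$cumulative_ewi, twi)

  totals <- dplyr::summarise(
    dplyr::group_by(category_summary, .data$group, .data$mode,
                    .data$scenario),
    total_ewi = total_ewi(.data$cumulative_ewi), .groups = "drop")
  totals$pct_twi <- pct_twi(totals$total_ewi, twi)
  totals$hazard_index <- hazard_index(totals$total_ewi, twi)

  structure(
    list(cells = cells, category_summary = category_summary,
         totals = totals, twi = twi, bound = bound),
    class = "pfas_risk"
  )
}

#' @export
print.pfas_risk <- function(x, ...) {
  cat("Cumulative PFAS dietary risk assessment (", x$bound,
      " occurrence bound, TWI = ", format(x$twi), " ng/kg bw per week)\n",
      sep = "")
  cat(nrow(x$cells), "exposure cells,",
      length(unique(x$cells$compound)), "compounds,",
      length(unique(x$category_summary$food_category)),
      "food categories\n\n")
  tot <- x$totals
  tot$total_ewi <- round_half_away(tot$total_ewi, 2)
  tot$pct_twi <- round_half_away(tot$pct_twi, 0)
  tot$hazard_index <- round_half_away(tot$hazard_index, 2)
  print(as.data.frame(tot), row.names = FALSE)
  invisible(x)
}
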