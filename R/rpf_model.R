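#' Resolve a compound's relative potency factor under a scenario
#'
#' Read-across compounds carry an RPF range; a coherent scenario sets every
#' range-valued compound at its minimum (`scenario = "min"`) or maximum
#' (`scenario = "max"`) simultaneously. Fixed-value compounds return the same
#' number under both scenarios.
#'
#' @param compound Character vector of compound identifiers (e.g. `"PFOA"`,
#'   `"PFDA"`).
#' @param scenario `"min"` or `"max"`.
#' @param rpf RPF table (tibble with `compound`, `rpf_min`, `rpf_max`);
#'   defaults to [default_rpf_table()].
#' @return Numeric vector of dimensionless RPFs, one per `compound`.
#' @examples
#' resolve_rpf("PFDA", "min")  # 4
#' resolve_rpf("PFDA", "max")  # 10
#' resolve_rpf("PFOA", "max")  # index compound, always 1
#' @export
resolve_rpf <- function(compound, scenario = c("min", "max"),
                        rpf = default_rpf_table()) {
  scenario <- match.arg(scenario)
  rpf <- validate_rpf_table(rpf)
  idx <- match(compound, rpf$compound)
  if (anyNA(idx)) {
    stop("no RPF assignment for compound(s): ",
         paste(unique(compound[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  if (scenario == "min") rpf$rpf_min[idx] else rpf$rpf_max[idx]
}

#' Weekly intake term for one compound in one food category
#'
#' The potency-weighted Estimated Weekly Intake contribution:
#'
#' \deqn{EWI_i = C_i \times RPF_i \times \frac{consumption}{BW} \times 7}
#'
#' with concentration in ng/kg food, consumption in g/day (converted to
#' kg/day internally), body weight in kg, and the factor 7 converting daily
#' to weekly intake. With `rpf = 1` this is the unweighted
#' concentration-based (CB) term.
#'
#' @param concentration Concentration in food, ng/kg (>= 0).
#' @param rpf Dimensionless relative potency factor (>= 0).
#' @param consumption Mean daily consumption of the food category, g/day
#'   (>= 0).
#' @param body_weight Body weight, kg (> 0).
#' @return Estimated weekly intake in ng/kg bw per week.
#' @examples
#' weekly_intake_term(1000, 2, 25.6, 70)  # 5.12
#' @export
weekly_intake_term <- function(concentration, rpf, consumption, body_weight) {
  if (any(concentration < 0) || any(rpf < 0) || any(consumption < 0)) {
    stop("concentration, rpf and consumption must be >= 0", call. = FALSE)
  }
  if (any(body_weight <= 0)) {
    stop("body_weight must be > 0", call. = FALSE)
  }
  concentration * rpf * (consumption / 1000) / body_weight * 7
}

#' Cumulative weekly intake for one food category
#'
#' Sums the unrounded per-compound weekly-intake terms of one food category,
#' consumer group, mode and scenario. Compounds without an occurrence record
#' simply contribute nothing. An empty set of terms is a valid degenerate
#' input and yields 0 with a warning.
#'
#' @param cells Either a numeric vector of per-compound EWI terms, or a data
#'   frame of exposure cells with an `ewi` column and (if present)
#'   homogeneous `food_category`, `group`, `mode` and `scenario` columns.
#' @return Cumulative EWI in ng/kg bw per week.
#' @examples
#' cumulative_ewi(c(0.03, 0.07, 0.12, 0.29, 0.03))
#' @export
cumulative_ewi <- function(cells) {
  if (is.data.frame(cells)) {
    for (col in intersect(c("food_category", "group", "mode", "scenario"),
                          names(cells))) {
      if (length(unique(cells[[col]])) > 1) {
        stop("cells mix more than one ", col,
             "; cumulate within a single stratum", call. = FALSE)
      }
    }
    cells <- cells$ewi
  }
  if (length(cells) == 0) {
    warning("no intake terms to cumulate; returning 0", call. = FALSE)
    return(0)
  }
  if (any(cells < 0)) stop("intake terms must be >= 0", call. = FALSE)
  sum(cells)
}

#' Total weekly intake across food categories
#'
#' Arithmetic sum of per-category cumulative EWIs for one consumer group,
#' mode and scenario.
#'
#' @param per_category Numeric vector (optionally named by food category) of
#'   per-category cumulative EWIs, ng/kg bw per week.
#' @return Total EWI in ng/kg bw per week.
#' @examples
#' total_ewi(c(milk_dairy = 0.54, meat = 4.11, eggs = 3.80,
#'             fish_seafood = 22.62))
#' @export
total_ewi <- function(per_category) {
  if (!is.numeric(per_category)) {
    stop("`per_category` must be numeric", call. = FALSE)
  }
  if (length(per_category) > length(food_categories())) {
    stop("more categories than the assessment defines", call. = FALSE)
  }
  if (any(per_category < 0)) {
    stop("cumulative EWIs must be >= 0", call. = FALSE)
  }
  sum(per_category)
}

#' Exposure as a percentage of the tolerable weekly intake
#'
#' @param ewi Estimated weekly intake, ng/kg bw per week.
#' @param twi Tolerable weekly intake, ng/kg bw per week (> 0); defaults to
#'   the EFSA group TWI of 4.4.
#' @return Unrounded percentage of the TWI; display rounding is the report
#'   layer's job ([round_report()]).
#' @examples
#' pct_twi(15.59)  # 354.3...%, reported as 354%
#' @export
pct_twi <- function(ewi, twi = twi_default()) {
  assert_scalar_number(twi, "twi")
  if (twi <= 0) stop("twi must be > 0", call. = FALSE)
  ewi / twi * 100
}

#' Hazard index of a total weekly intake
#'
#' Ratio of total exposure to the health-based guidance value (the hazard
#' quotient of the mixture expressed in index-compound equivalents). Values
#' above 1 flag potential health concern.
#'
#' @param total Total EWI, ng/kg bw per week.
#' @param twi Tolerable weekly intake, ng/kg bw per week (> 0).
#' @return Dimensionless hazard index, unrounded.
#' @examples
#' hazard_index(31.07)  # 7.06...
#' @export
hazard_index <- function(total, twi = twi_default()) {
  assert_scalar_number(twi, "twi")
  if (twi <= 0) stop("twi must be > 0", call. = FALSE)
  total / twi
}

#' Back-derive a concentration from a weekly intake term
#'
#' Inverts the weekly-intake equation, recovering the food concentration
#' that produces a given EWI term under known RPF, consumption and body
#' weight. Used for fixture diagnostics and round-trip testing; not part of
#' the assessment itself.
#'
#' @inheritParams weekly_intake_term
#' @param ewi Weekly intake term, ng/kg bw per week.
#' @return Concentration in ng/kg food.
#' @examples
#' back_derive_concentration(5.12, 2, 25.6, 70)  # 1000
#' @export
back_derive_concentration <- function(ewi, rpf, consumption, body_weight) {
  if (any(rpf <= 0) || any(consumption <= 0)) {
    stop("cannot invert the intake equation with rpf = 0 or consumption = 0",
         call. = FALSE)
  }
  if (any(body_weight <= 0)) stop("body_weight must be > 0", call. = FALSE)
  if (any(ewi < 0)) stop("ewi must be >= 0", call. = FALSE)
  ewi / (rpf * (consumption / 1000) / body_weight * 7)
}
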