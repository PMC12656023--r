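#' Engine constants: food categories, population groups, TWI
#'
#' The assessment covers the four animal-derived food categories and four
#' European consumer groups of the EFSA Comprehensive Food Consumption
#' Database extraction, and characterises risk against the EFSA (2020) group
#' Tolerable Weekly Intake for PFAS.
#'
#' @return `food_categories()` and `population_groups()` return character
#'   vectors of the valid level names; `twi_default()` returns the group TWI
#'   in ng/kg bw per week.
#' @examples
#' food_categories()
#' twi_default()
#' @name constants
NULL

#' @rdname constants
#' @export
food_categories <- function() {
  c("fish_seafood", "meat", "eggs", "milk_dairy")
}

#' @rdname constants
#' @export
population_groups <- function() {
  c("toddlers", "adolescents", "adults", "elderly")
}

#' @rdname constants
#' @export
twi_default <- function() 4.4

#' Standard body weights per population group
#'
#' EFSA default body weights: 12 kg for toddlers, 45 kg for adolescents and
#' 70 kg for adults and the elderly.
#'
#' @return Named numeric vector of body weights in kg, one entry per
#'   population group.
#' @examples
#' default_body_weights()
#' @export
default_body_weights <- function() {
  c(toddlers = 12, adolescents = 45, adults = 70, elderly = 70)
}

#' Default relative potency factor table
#'
#' Ships the liver-hypertrophy RPF set of Bil and colleagues as used in the
#' reference assessment: fixed values for data-rich compounds (PFOA = 1 as
#' index compound) and min--max ranges from read-across for data-poor
#' homologues (PFHpS, PFPeS, PFTrDA).
#'
#' PFPeA is a special case: the published RPF grid prints 0, but the
#' reference assessment's milk/dairy intake results are only reproducible
#' with the hepatic reference point of 0.03 quoted in its discussion. The
#' default therefore ships 0.03; set `pfpea_rpf = "literal"` to use the
#' printed 0.
#'
#' @param pfpea_rpf Either `"hepatic"` (default; PFPeA RPF = 0.03) or
#'   `"literal"` (PFPeA RPF = 0 as printed in the RPF grid).
#' @return A tibble with columns `compound`, `rpf_min`, `rpf_max`,
#'   `read_across`.
#' @examples
#' default_rpf_table()
#' @export
default_rpf_table <- function(pfpea_rpf = c("hepatic", "literal")) {
  pfpea_rpf <- match.arg(pfpea_rpf)
  rpf <- read_rpf_table(reference_path("rpf.csv"))
  if (pfpea_rpf == "literal") {
    rpf$rpf_min[rpf$compound == "PFPeA"] <- 0
    rpf$rpf_max[rpf$compound == "PFPeA"] <- 0
  }
  rpf
}

#' Default European mean consumption table
#'
#' Survey-weighted European mean consumption (g/day) of the four
#' animal-derived food categories for each consumer group.
#'
#' @return A tibble with columns `food_category`, `group`,
#'   `mean_consumption` (g/day), covering the complete 4 x 4 grid.
#' @examples
#' default_consumption_table()
#' @export
default_consumption_table <- function() {
  read_consumption_table(reference_path("consumption.csv"))
}

reference_path <- function(file) {
  path <- system.file("extdata", "reference", file, package = "mixpeq")
  if (!nzchar(path)) {
    stop("reference data file not found: ", file, call. = FALSE)
  }
  path
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
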