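#' Read and validate input tables
#'
#' CSV readers for the four input table formats of the engine. Each reader
#' checks the header, coerces types, validates domain invariants
#' (non-negative concentrations, `rpf_min <= rpf_max`, known food categories
#' and consumer groups, censoring consistency) and returns a tibble.
#'
#' Expected columns:
#' * `read_rpf_table()`: `compound,rpf_min,rpf_max,read_across`
#' * `read_occurrence_table()`:
#'   `compound,food_category,mean_lb_ng_per_kg,mean_ub_ng_per_kg`
#'   (the UB column is optional and may be empty)
#' * `read_consumption_table()`: `food_category,group,mean_consumption_g_day`
#' * `read_sample_records()`:
#'   `compound,food_category,value_ng_per_kg,censored,lod_ng_per_kg,loq_ng_per_kg`
#' * `read_survey_table()`:
#'   `survey_id,food_category,group,mean_consumption_g_day,weight`
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated tibble (columns renamed to the engine's internal
#'   names: `mean_lb`, `mean_ub`, `mean_consumption`, `value`, `lod`, `loq`).
#' @name table-readers
NULL

read_checked_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in optional) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  tibble::as_tibble(df[, c(required, optional), drop = FALSE])
}

check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop("unknown ", what, ": ", paste(bad, collapse = ", "),
         " (expected one of ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(x)
}

#' @rdname table-readers
#' @export
read_rpf_table <- function(path) {
  rpf <- read_checked_csv(path, c("compound", "rpf_min", "rpf_max",
                                  "read_across"))
  rpf$read_across <- as.logical(rpf$read_across)
  validate_rpf_table(rpf)
}

validate_rpf_table <- function(rpf) {
  stopifnot(is.data.frame(rpf),
            all(c("compound", "rpf_min", "rpf_max") %in% names(rpf)))
  if (anyDuplicated(rpf$compound)) {
    stop("duplicated compound in RPF table", call. = FALSE)
  }
  if (any(rpf$rpf_min < 0) || any(rpf$rpf_max < 0)) {
    stop("RPFs must be >= 0", call. = FALSE)
  }
  if (any(rpf$rpf_min > rpf$rpf_max)) {
    stop("rpf_min must not exceed rpf_max", call. = FALSE)
  }
  if ("PFOA" %in% rpf$compound) {
    idx <- rpf$compound == "PFOA"
    if (any(rpf$rpf_min[idx] != 1) || any(rpf$rpf_max[idx] != 1)) {
      stop("index compound PFOA must have RPF fixed at 1", call. = FALSE)
    }
  }
  tibble::as_tibble(rpf)
}

#' @rdname table-readers
#' @export
read_occurrence_table <- function(path) {
  occ <- read_checked_csv(path,
                          c("compound", "food_category", "mean_lb_ng_per_kg"),
                          "mean_ub_ng_per_kg")
  names(occ)[names(occ) == "mean_lb_ng_per_kg"] <- "mean_lb"
  names(occ)[names(occ) == "mean_ub_ng_per_kg"] <- "mean_ub"
  validate_occurrence_table(occ)
}

validate_occurrence_table <- function(occ) {
  stopifnot(is.data.frame(occ),
            all(c("compound", "food_category", "mean_lb") %in% names(occ)))
  if (!"mean_ub" %in% names(occ)) occ$mean_ub <- NA_real_
  check_levels(occ$food_category, food_categories(), "food_category")
  if (any(occ$mean_lb < 0, na.rm = TRUE)) {
    stop("mean_lb must be >= 0", call. = FALSE)
  }
  ub_known <- !is.na(occ$mean_ub)
  if (any(occ$mean_lb[ub_known] > occ$mean_ub[ub_known])) {
    stop("mean_lb must not exceed mean_ub", call. = FALSE)
  }
  if (anyDuplicated(occ[, c("compound", "food_category")])) {
    stop("duplicated compound x food_category in occurrence table",
         call. = FALSE)
  }
  tibble::as_tibble(occ)
}

#' @rdname table-readers
#' @export
read_consumption_table <- function(path) {
  cons <- read_checked_csv(path, c("food_category", "group",
                                   "mean_consumption_g_day"))
  names(cons)[names(cons) == "mean_consumption_g_day"] <- "mean_consumption"
  validate_consumption_table(cons)
}

validate_consumption_table <- function(cons) {
  stopifnot(is.data.frame(cons),
            all(c("food_category", "group", "mean_consumption") %in%
                  names(cons)))
  check_levels(cons$food_category, food_categories(), "food_category")
  check_levels(cons$group, population_groups(), "group")
  if (any(cons$mean_consumption < 0)) {
    stop("mean_consumption must be >= 0", call. = FALSE)
  }
  if (anyDuplicated(cons[, c("food_category", "group")])) {
    stop("duplicated food_category x group in consumption table",
         call. = FALSE)
  }
  tibble::as_tibble(cons)
}

#' @rdname table-readers
#' @export
read_sample_records <- function(path) {
  smp <- read_checked_csv(path, c("compound", "food_category", "censored"),
                          c("value_ng_per_kg", "lod_ng_per_kg",
                            "loq_ng_per_kg"))
  names(smp)[names(smp) == "value_ng_per_kg"] <- "value"
  names(smp)[names(smp) == "lod_ng_per_kg"] <- "lod"
  names(smp)[names(smp) == "loq_ng_per_kg"] <- "loq"
  smp$censored <- as.logical(smp$censored)
  validate_sample_records(smp)
}

validate_sample_records <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("compound", "food_category", "censored") %in%
                  names(samples)))
  for (col in c("value", "lod", "loq")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_real_
  }
  check_levels(samples$food_category, food_categories(), "food_category")
  cens <- samples$censored
  if (any(is.na(cens))) stop("censored flag must be TRUE/FALSE", call. = FALSE)
  if (any(!cens & is.na(samples$value))) {
    stop("quantified records must carry a value", call. = FALSE)
  }
  if (any(!cens & samples$value < 0, na.rm = TRUE)) {
    stop("quantified values must be >= 0", call. = FALSE)
  }
  if (any(cens & !is.na(samples$value))) {
    stop("censored records must not carry a value", call. = FALSE)
  }
  if (any(cens & is.na(samples$lod) & is.na(samples$loq))) {
    stop("censored records need at least one of lod/loq", call. = FALSE)
  }
  tibble::as_tibble(samples)
}

#' @rdname table-readers
#' @export
read_survey_table <- function(path) {
  srv <- read_checked_csv(path, c("survey_id", "food_category", "group",
                                  "mean_consumption_g_day", "weight"))
  names(srv)[names(srv) == "mean_consumption_g_day"] <- "mean_consumption"
  validate_survey_table(srv)
}

validate_survey_table <- function(surveys) {
  stopifnot(is.data.frame(surveys),
            all(c("food_category", "group", "mean_consumption", "weight")
                %in% names(surveys)))
  check_levels(surveys$food_category, food_categories(), "food_category")
  check_levels(surveys$group, population_groups(), "group")
  if (any(surveys$weight <= 0)) stop("survey weights must be > 0",
                                     call. = FALSE)
  if (any(surveys$mean_consumption < 0)) {
    stop("mean_consumption must be >= 0", call. = FALSE)
  }
  tibble::as_tibble(surveys)
}
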