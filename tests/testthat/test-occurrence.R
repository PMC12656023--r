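make_samples <- function(values = numeric(), n_censored = 0, lod = NA_real_,
                         loq = NA_real_, compound = "PFOS",
                         food_category = "fish_seafood") {
  n <- length(values) + n_censored
  tibble::tibble(
    compound = compound, food_category = food_category,
    value = c(values, rep(NA_real_, n_censored)),
    censored = c(rep(FALSE, length(values)), rep(TRUE, n_censored)),
    lod = c(rep(NA_real_, length(values)), rep(lod, n_censored)),
    loq = c(rep(NA_real_, length(values)), rep(loq, n_censored))
  )
}

test_that("bound_mean substitutes 0 (LB) and LOQ/LOD (UB) for non-detects", {
  smp <- make_samples(values = 100, n_censored = 1, lod = 10)
  expect_equal(bound_mean(smp, "LB"), 50)
  expect_equal(bound_mean(smp, "UB"), 55)
  all_cens <- make_samples(n_censored = 2, loq = 20)
  expect_equal(bound_mean(all_cens, "UB"), 20)
  expect_equal(bound_mean(all_cens, "LB"), 0)
  # UB prefers LOQ over LOD when both are reported
  both <- make_samples(n_censored = 1, lod = 5, loq = 20)
  expect_equal(bound_mean(both, "UB"), 20)
  # fully quantified: bounds coincide
  quant <- make_samples(values = c(10, 30))
  expect_equal(bound_mean(quant, "LB"), bound_mean(quant, "UB"))
  no_limit <- tibble::tibble(compound = "PFOS",
                             food_category = "fish_seafood",
                             value = NA_real_, censored = TRUE,
                             lod = NA_real_, loq = NA_real_)
  expect_error(bound_mean(no_limit, "LB"), "lod/loq")
  mixed <- dplyr::bind_rows(make_samples(values = 1),
                            make_samples(values = 1, compound = "PFOA"))
  expect_error(bound_mean(mixed, "LB"), "more than one compound")
})

test_that("LB mean never exceeds UB mean; equality iff nothing censored", {
  set.seed(11)
  for (i in 1:25) {
    n_pos <- sample(0:10, 1)
    n_cen <- sample(0:10, 1)
    if (n_pos + n_cen == 0) n_pos <- 1
    smp <- make_samples(values = rlnorm(n_pos, 3, 1), n_censored = n_cen,
                        lod = runif(1, 1, 5), loq = runif(1, 5, 20))
    lb <- bound_mean(smp, "LB")
    ub <- bound_mean(smp, "UB")
    expect_lte(lb, ub)
    if (n_cen == 0) expect_equal(lb, ub) else expect_lt(lb, ub)
  }
})

test_that("adding censored records dilutes the LB mean", {
  positives <- c(50, 150, 400)
  lb <- vapply(0:6, function(k) {
    bound_mean(make_samples(values = positives, n_censored = k, lod = 5),
               "LB")
  }, numeric(1))
  expect_true(all(diff(lb) < 0))
})

test_that("weighted_mean_consumption pools surveys by weight", {
  srv <- tibble::tibble(survey_id = c("a", "b"), food_category = "meat",
                        group = "adults", mean_consumption = c(10, 30),
                        weight = c(100, 300))
  expect_equal(weighted_mean_consumption(srv), 25)
  expect_equal(weighted_mean_consumption(srv[1, ]), 10)
  sym <- tibble::tibble(survey_id = c("a", "b"), food_category = "meat",
                        group = "adults", mean_consumption = c(9, 11),
                        weight = c(7, 7))
  expect_equal(weighted_mean_consumption(sym), 10)
  # always inside the range of survey means
  set.seed(3)
  for (i in 1:10) {
    s <- tibble::tibble(survey_id = letters[1:5], food_category = "eggs",
                        group = "elderly",
                        mean_consumption = runif(5, 0, 50),
                        weight = runif(5, 1, 1000))
    wm <- weighted_mean_consumption(s)
    expect_gte(wm, min(s$mean_consumption))
    expect_lte(wm, max(s$mean_consumption))
  }
  expect_error(weighted_mean_consumption(srv[0, ]), "at least one")
})

test_that("single back-derived PFOS fish concentration reproduces the
           adult intake it was derived from", {
  conc <- back_derive_concentration(7.72, 2, 25.6, 70)
  occ <- tibble::tibble(compound = "PFOS", food_category = "fish_seafood",
                        mean_lb = conc, mean_ub = NA_real_)
  risk <- suppressWarnings(build_exposure_table(occ, groups = "adults",
                                                mode = "PEQ"))
  cell <- risk$cells[risk$cells$scenario == "min", ]
  expect_equal(cell$ewi, 7.72, tolerance = 1e-12)
  expect_equal(round_half_away(cell$pct_twi), 175)
})

test_that("empty occurrence yields all-zero summaries and HI 0", {
  occ <- tibble::tibble(compound = character(), food_category = character(),
                        mean_lb = numeric(), mean_ub = numeric())
  risk <- build_exposure_table(occ)
  expect_equal(nrow(risk$cells), 0)
  expect_true(all(risk$category_summary$cumulative_ewi == 0))
  expect_true(all(risk$totals$hazard_index == 0))
})

test_that("compounds without an RPF fail loudly unless skip-listed", {
  occ <- tibble::tibble(compound = c("PFOS", "NOVEL"),
                        food_category = "meat", mean_lb = c(100, 50),
                        mean_ub = NA_real_)
  expect_error(build_exposure_table(occ), "NOVEL")
  expect_warning(
    withCallingHandlers(
      risk <- build_exposure_table(occ, skip_compounds = "NOVEL",
                                   groups = "adults"),
      warning = function(w) {
        if (grepl("no occurrence records", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    "dropping"
  )
  expect_false("NOVEL" %in% risk$cells$compound)
})

test_that("missing categories warn and contribute zero to the total", {
  occ <- tibble::tibble(compound = "PFOS", food_category = "meat",
                        mean_lb = 100, mean_ub = NA_real_)
  expect_warning(risk <- build_exposure_table(occ, groups = "adults"),
                 "no occurrence records")
  summ <- risk$category_summary
  expect_equal(summ$cumulative_ewi[summ$food_category == "eggs"],
               rep(0, 4))
  meat <- summ[summ$food_category == "meat" & summ$mode == "PEQ" &
                 summ$scenario == "min", ]
  tot <- risk$totals[risk$totals$mode == "PEQ" &
                       risk$totals$scenario == "min", ]
  expect_equal(tot$total_ewi, meat$cumulative_ewi)
})

test_that("CB mode equals PEQ mode with every RPF forced to one", {
  tabs <- random_tables(seed = 101)
  unit_rpf <- tabs$rpf
  unit_rpf$rpf_min <- 1
  unit_rpf$rpf_max <- 1
  cb <- suppressWarnings(build_exposure_table(
    tabs$occurrence, tabs$rpf, tabs$consumption, mode = "CB",
    scenario = "min"))
  peq1 <- suppressWarnings(build_exposure_table(
    tabs$occurrence, unit_rpf, tabs$consumption, mode = "PEQ",
    scenario = "min"))
  expect_equal(cb$cells$ewi, peq1$cells$ewi)
  expect_equal(cb$totals$total_ewi, peq1$totals$total_ewi)
  # and within one run, CB is scenario-invariant
  both <- suppressWarnings(build_exposure_table(
    tabs$occurrence, tabs$rpf, tabs$consumption, mode = "CB"))
  cbmin <- both$totals[both$totals$scenario == "min", ]
  cbmax <- both$totals[both$totals$scenario == "max", ]
  expect_equal(cbmin$total_ewi, cbmax$total_ewi)
})

test_that("scaling every concentration by k scales all results by k", {
  tabs <- random_tables(seed = 202)
  base <- suppressWarnings(build_exposure_table(
    tabs$occurrence, tabs$rpf, tabs$consumption))
  k <- 3.7
  occ_k <- tabs$occurrence
  occ_k$mean_lb <- occ_k$mean_lb * k
  occ_k$mean_ub <- occ_k$mean_ub * k
  scaled <- suppressWarnings(build_exposure_table(
    occ_k, tabs$rpf, tabs$consumption))
  expect_equal(scaled$cells$ewi, base$cells$ewi * k)
  expect_equal(scaled$totals$total_ewi, base$totals$total_ewi * k)
  expect_equal(scaled$totals$hazard_index, base$totals$hazard_index * k)
  expect_equal(scaled$totals$pct_twi, base$totals$pct_twi * k)
})

test_that("min scenario never exceeds max; equal without ranged compounds", {
  tabs <- random_tables(seed = 303)
  risk <- suppressWarnings(build_exposure_table(
    tabs$occurrence, tabs$rpf, tabs$consumption, mode = "PEQ"))
  summ <- tidyr::pivot_wider(risk$category_summary,
                             names_from = "scenario",
                             values_from = c("cumulative_ewi", "pct_twi"))
  expect_true(all(summ$cumulative_ewi_min <= summ$cumulative_ewi_max + 1e-12))
  fixed <- tabs$rpf
  fixed$rpf_max <- fixed$rpf_min
  risk2 <- suppressWarnings(build_exposure_table(
    tabs$occurrence, fixed, tabs$consumption, mode = "PEQ"))
  s2 <- tidyr::pivot_wider(risk2$category_summary,
                           names_from = "scenario",
                           values_from = c("cumulative_ewi", "pct_twi"))
  expect_equal(s2$cumulative_ewi_min, s2$cumulative_ewi_max)
})

test_that("vectorized engine matches the naive per-record oracle", {
  for (seed in c(1, 2)) {
    tabs <- random_tables(n_compounds = 10, seed = seed)
    for (m in c("PEQ", "CB")) {
      for (s in c("min", "max")) {
        risk <- suppressWarnings(build_exposure_table(
          tabs$occurrence, tabs$rpf, tabs$consumption,
          tabs$body_weights, mode = m, scenario = s))
        oracle <- naive_assessment(tabs$occurrence, tabs$rpf,
                                   tabs$consumption, tabs$body_weights,
                                   m, s)
        eng <- risk$cells[order(risk$cells$compound,
                                risk$cells$food_category,
                                risk$cells$group), ]
        orc <- oracle$cells[order(oracle$cells$compound,
                                  oracle$cells$food_category,
                                  oracle$cells$group), ]
        expect_equal(eng$ewi, orc$ewi, tolerance = 1e-12)
        for (g in unique(risk$totals$group)) {
          expect_equal(
            risk$totals$total_ewi[risk$totals$group == g],
            oracle$totals[[g]]$total, tolerance = 1e-12)
          expect_equal(
            risk$totals$hazard_index[risk$totals$group == g],
            oracle$totals[[g]]$hi, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("build_exposure_table is deterministic", {
  tabs <- random_tables(seed = 404)
  a <- suppressWarnings(build_exposure_table(tabs$occurrence, tabs$rpf,
                                             tabs$consumption))
  b <- suppressWarnings(build_exposure_table(tabs$occurrence, tabs$rpf,
                                             tabs$consumption))
  expect_identical(a$cells, b$cells)
  expect_identical(a$totals, b$totals)
})

test_that("UB bound uses mean_ub and requires it", {
  occ <- tibble::tibble(compound = "PFOS", food_category = "meat",
                        mean_lb = 100, mean_ub = 250)
  lb <- suppressWarnings(build_exposure_table(occ, groups = "adults",
                                              mode = "CB", bound = "LB"))
  ub <- suppressWarnings(build_exposure_table(occ, groups = "adults",
                                              mode = "CB", bound = "UB"))
  expect_equal(ub$cells$ewi / lb$cells$ewi, rep(2.5, nrow(ub$cells)))
  occ$mean_ub <- NA_real_
  expect_error(suppressWarnings(build_exposure_table(
    occ, groups = "adults", bound = "UB")), "mean_ub")
})
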