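# Naive per-record oracle: recomputes the whole assessment with explicit
# loops and scalar arithmetic, independently of the vectorized engine.
naive_assessment <- function(occurrence, rpf, consumption, body_weights,
                             mode, scenario, twi = 4.4) {
  cells <- data.frame()
  for (i in seq_len(nrow(occurrence))) {
    comp <- occurrence$compound[i]
    cat_ <- occurrence$food_category[i]
    conc <- occurrence$mean_lb[i]
    cons_rows <- consumption[consumption$food_category == cat_, ]
    for (j in seq_len(nrow(cons_rows))) {
      g <- cons_rows$group[j]
      if (mode == "PEQ") {
        k <- which(rpf$compound == comp)
        r <- if (scenario == "min") rpf$rpf_min[k] else rpf$rpf_max[k]
      } else {
        r <- 1
      }
      ewi <- conc * r * (cons_rows$mean_consumption[j] / 1000) /
        body_weights[[g]] * 7
      cells <- rbind(cells, data.frame(
        compound = comp, food_category = cat_, group = g, ewi = ewi))
    }
  }
  totals <- list()
  for (g in unique(consumption$group)) {
    tot <- 0
    for (cat_ in unique(consumption$food_category)) {
      sub <- cells[cells$group == g & cells$food_category == cat_, ]
      tot <- tot + sum(sub$ewi)
    }
    totals[[g]] <- list(total = tot, hi = tot / twi)
  }
  list(cells = cells, totals = totals)
}

# small random-but-reproducible input tables for property tests
random_tables <- function(n_compounds = 6, seed = 1) {
  set.seed(seed)
  compounds <- sprintf("CMP%02d", seq_len(n_compounds))
  rpf_min <- round(runif(n_compounds, 0, 4), 3)
  ranged <- runif(n_compounds) < 0.5
  rpf <- tibble::tibble(
    compound = compounds,
    rpf_min = rpf_min,
    rpf_max = ifelse(ranged, rpf_min + round(runif(n_compounds, 0, 6), 3),
                     rpf_min),
    read_across = ranged
  )
  occ <- tidyr::expand_grid(compound = compounds,
                            food_category = food_categories())
  occ <- occ[runif(nrow(occ)) < 0.8, ]
  occ$mean_lb <- round(rlnorm(nrow(occ), log(200), 1), 2)
  occ$mean_ub <- occ$mean_lb * (1 + round(runif(nrow(occ), 0, 2), 2))
  list(rpf = rpf, occurrence = tibble::as_tibble(occ),
       consumption = default_consumption_table(),
       body_weights = default_body_weights())
}
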