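#' Unseen deaths implied by an under-reporting proportion
#'
#' If a proportion `p` of true under-5 deaths goes unreported, the observed
#' count is `(1 - p)` times the true count; the unseen number is therefore
#' `observed * p / (1 - p)`, rounded to an integer with banker's (half to
#' even) rounding.
#'
#' @param observed observed under-5 death count(s).
#' @param p assumed under-reporting proportion in `[0, 1)`.
#' @export
unseen_deaths <- function(observed, p) {
  if (any(p < 0) || any(p >= 1)) stop("p must lie in [0, 1)")
  round(observed * p / (1 - p))
}

#' Population/displacement bias grid
#'
#' Re-estimates excess mortality for each combination of a multiplicative
#' bias on the census-anchor populations and on the displacement flow
#' counts: anchors and flows are scaled, denominators rebuilt for the
#' actual and the counterfactual arm, and the bootstrap re-run with the
#' same seed (so the (1, 1) cell reproduces the baseline exactly).
#'
#' @param state pipeline state, as returned by [run_all()] (or a list with
#'   the same `model_cdr`, `panel`, `districts`, `anchors`, `flows` and
#'   `config` elements).
#' @param pop_mult,disp_mult bias multipliers (> 0).
#' @param scenario scenario name (default `"most_likely"`).
#' @param B bootstrap sets per cell (reduced for tractability).
#' @param seed integer seed.
#' @return tidy data.frame: `pop_mult`, `disp_mult`, overall excess `mode`,
#'   `mean`, `lci`, `uci`.
#' @export
run_bias_grid <- function(state, pop_mult = c(0.8, 1.0, 1.2),
                          disp_mult = c(0.5, 1.0, 2.0),
                          scenario = "most_likely", B = 500L, seed = 1L) {
  stopifnot(all(pop_mult > 0), all(disp_mult > 0))
  grid <- expand.grid(pop_mult = pop_mult, disp_mult = disp_mult,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    anchors <- lapply(state$anchors, function(a) {
      a$population <- a$population * grid$pop_mult[i]; a
    })
    flows <- state$flows
    flows$persons <- round(flows$persons * grid$disp_mult[i])
    boot <- excess_for_inputs(state$model_cdr, state$panel, state$districts,
                              anchors, flows, scenario_spec(scenario),
                              state$config, B = B, seed = seed)
    s <- summarize_excess(boot, "overall", alpha = state$config$alpha)
    data.frame(pop_mult = grid$pop_mult[i], disp_mult = grid$disp_mult[i],
               mode = s$mode, mean = s$mean, lci = s$lci, uci = s$uci)
  })
  do.call(rbind, rows)
}

#' Under-reporting sensitivity: reattribute unseen deaths and re-run
#'
#' For an assumed under-reporting proportion `p`, computes each survey's
#' unseen under-5 deaths, and over `R` replicates: allocates them
#' multinomially across the survey's households with probability
#' proportional to under-5 person-time, refits the under-5 mortality model
#' on the augmented data, and recomputes the plug-in excess death toll.
#' Replicate summaries (histogram mode and percentile interval) describe
#' the induced uncertainty.  `p = 0` reproduces the baseline plug-in
#' estimate in every replicate.
#'
#' @param state pipeline state (see [run_bias_grid()]); must carry
#'   `model_data` and the selected spec's terms.
#' @param p under-reporting proportion in `[0, 1)`.
#' @param R replicates (default 200; the full analysis used 10,000).
#' @param scenario scenario name.
#' @param seed integer seed.
#' @return list: `summary` (mode/mean/lci/uci of the U5 excess toll) and
#'   `replicates` (numeric vector of length `R`).
#' @export
reattribute_and_rerun <- function(state, p, R = 200L,
                                  scenario = "most_likely", seed = 1L) {
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  data <- state$model_data
  cfg <- state$config
  spec <- model_spec("U5DR", state$model_cdr$spec$terms)
  by_survey <- split(seq_len(nrow(data)), data$survey_id)
  unseen <- vapply(by_survey, function(i)
    unseen_deaths(sum(data$deaths_u5[i]), p), 0)
  prep <- prepared_excess_inputs(state, scenario_spec(scenario))
  reps <- with_seed(seed, vapply(seq_len(R), function(r) {
    d2 <- data
    for (s in names(by_survey)) {
      u <- unseen[[s]]
      if (u == 0) next
      i <- by_survey[[s]]
      w <- d2$pd_u5[i]
      if (sum(w) <= 0) stop("survey ", s, " has zero under-5 person-time")
      add <- as.vector(stats::rmultinom(1L, u, prob = w))
      d2$deaths_u5[i] <- d2$deaths_u5[i] + add
      d2$deaths[i] <- d2$deaths[i] + add
    }
    fit <- fit_quasipoisson(d2, spec)
    plug_in_excess(fit, prep)
  }, 0))
  q <- stats::quantile(reps, c(cfg$alpha / 2, 1 - cfg$alpha / 2), type = 7,
                       names = FALSE)
  list(summary = data.frame(p = p, mode = mode_estimate(reps),
                            mean = mean(reps), lci = q[1], uci = q[2]),
       replicates = reps)
}

# Actual/counterfactual design pieces shared by every re-run at fixed
# denominators (under-reporting sensitivity refits only the model).
prepared_excess_inputs <- function(state, scenario) {
  cfg <- state$config
  flows_cf <- apply_displacement_rule(state$flows, scenario$displacement,
                                      cfg$apply_from)
  pop_act <- build_population_series(state$anchors, state$flows,
                                     cfg$month_range, cfg$growth_rate_yr,
                                     cfg$under5_fraction)
  pop_cf <- build_population_series(state$anchors, flows_cf,
                                    cfg$month_range, cfg$growth_rate_yr,
                                    cfg$under5_fraction)
  panel_cf <- build_counterfactual(state$panel, scenario,
                                   cfg$reference_years, cfg$apply_from)
  list(panel_act = state$panel, panel_cf = panel_cf,
       districts = state$districts, pop_act = pop_act, pop_cf = pop_cf,
       months = cfg$excess_months)
}

# Point-estimate excess over the excess months (no coefficient sampling).
plug_in_excess <- function(model, prep) {
  act <- predict_tolls(model, prep$panel_act, prep$districts, prep$pop_act,
                       prep$months)
  cf <- predict_tolls(model, prep$panel_cf, prep$districts, prep$pop_cf,
                      prep$months)
  sum(act$expected_deaths) - sum(cf$expected_deaths)
}
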