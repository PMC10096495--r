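#' Counterfactual scenario specification
#'
#' Bundles, per model predictor, the rule used to construct its no-crisis
#' counterfactual values, plus the displacement rule applied to the flow
#' table before denominators are rebuilt.  The three named scenarios are
#' defined as follows: the most likely scenario sets SAM,
#' measles and malaria to their month-specific 2014-2016 medians within
#' each stratum and conflict to its plain 2014-2016 median, removing
#' drought-attributed displacement; the worst case keeps conflict and
#' measles as observed, raises SAM to the month-specific 75th percentile
#' and cuts malaria to 25% of actuality (higher malaria predicted lower
#' mortality); the best case lowers SAM to the 25th percentile, removes
#' measles entirely, keeps malaria as observed, cuts conflict to 25% and
#' removes all new displacement.  Refugee flows stay as observed in every
#' scenario.
#'
#' @param name `"most_likely"`, `"worst_case"`, `"best_case"`, or
#'   `"custom"`.
#' @param rules for `"custom"`: named list predictor -> list with `rule` in
#'   `month_specific_median`, `month_specific_p75`, `month_specific_p25`,
#'   `median`, `as_actual`, `fraction_of_actual` (with element `q` in
#'   (0, 1]), `zero`.
#' @param displacement for `"custom"`: one of `no_drought_displacement`,
#'   `as_actual`, `no_new_displacement`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("most_likely", "worst_case", "best_case",
                                   "custom"),
                          rules = NULL, displacement = NULL) {
  name <- match.arg(name)
  presets <- list(
    most_likely = list(
      rules = list(sam = list(rule = "month_specific_median"),
                   measles = list(rule = "month_specific_median"),
                   malaria = list(rule = "month_specific_median"),
                   conflict = list(rule = "median")),
      displacement = "no_drought_displacement"),
    worst_case = list(
      rules = list(sam = list(rule = "month_specific_p75"),
                   measles = list(rule = "as_actual"),
                   malaria = list(rule = "fraction_of_actual", q = 0.25),
                   conflict = list(rule = "as_actual")),
      displacement = "as_actual"),
    best_case = list(
      rules = list(sam = list(rule = "month_specific_p25"),
                   measles = list(rule = "zero"),
                   malaria = list(rule = "as_actual"),
                   conflict = list(rule = "fraction_of_actual", q = 0.25)),
      displacement = "no_new_displacement"))
  if (name != "custom") {
    rules <- presets[[name]]$rules
    displacement <- presets[[name]]$displacement
  }
  if (is.null(rules) || is.null(displacement))
    stop("custom scenarios need explicit rules and a displacement rule")
  for (r in rules) {
    if (identical(r$rule, "fraction_of_actual") &&
        (is.null(r$q) || r$q <= 0 || r$q > 1))
      stop("fraction_of_actual requires q in (0, 1]")
  }
  stopifnot(displacement %in% c("no_drought_displacement", "as_actual",
                                "no_new_displacement"))
  structure(list(name = name, rules = rules, displacement = displacement),
            class = "scenario_spec")
}

#' Build a counterfactual predictor panel
#'
#' Replaces, from `apply_from` onwards, each ruled predictor's values with
#' the scenario's counterfactual: month-specific rules take the stated
#' statistic of the district's values at the same calendar month across the
#' reference years (falling back to the region-level statistic where the
#' district has no reference value); plain `median` pools all reference
#' months; fraction rules scale actual values; `zero` clears them.
#' Percentiles use linear-interpolation (type 7) quantiles.  Values before
#' `apply_from` are left untouched.
#'
#' @param panel wide continuous predictor panel (`district`, `ym`, columns).
#' @param scenario a [scenario_spec()].
#' @param reference_years integer vector of pre-crisis reference years
#'   (default 2014:2016).
#' @param apply_from first month index the counterfactual applies to
#'   (default January 2017).
#' @param region optional named vector district -> region for the fallback.
#' @return panel of identical shape with counterfactual values.
#' @export
build_counterfactual <- function(panel, scenario,
                                 reference_years = 2014:2016,
                                 apply_from = ym("2017-01"),
                                 region = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  yr <- ym_year(panel$ym)
  if (!any(yr %in% reference_years))
    stop("panel does not cover the reference years")
  moy <- ym_month(panel$ym)
  out <- panel
  for (p in names(scenario$rules)) {
    if (!p %in% names(panel)) next
    r <- scenario$rules[[p]]
    if (r$rule == "as_actual") next
    tgt <- panel$ym >= apply_from
    ref <- yr %in% reference_years
    out[[p]][tgt] <- switch(r$rule,
      zero = 0,
      fraction_of_actual = r$q * panel[[p]][tgt],
      median = {
        med <- tapply(panel[[p]][ref], panel$district[ref],
                      stats::median, na.rm = TRUE)
        as.numeric(med[panel$district[tgt]])
      },
      month_specific_median = ,
      month_specific_p25 = ,
      month_specific_p75 = {
        prob <- c(month_specific_median = 0.5, month_specific_p25 = 0.25,
                  month_specific_p75 = 0.75)[[r$rule]]
        key_ref <- paste(panel$district[ref], moy[ref])
        stat <- tapply(panel[[p]][ref], key_ref, stats::quantile,
                       probs = prob, na.rm = TRUE, type = 7, names = FALSE)
        v <- as.numeric(stat[paste(panel$district[tgt], moy[tgt])])
        if (anyNA(v) && !is.null(region)) {
          rkey_ref <- paste(region[panel$district[ref]], moy[ref])
          rstat <- tapply(panel[[p]][ref], rkey_ref, stats::quantile,
                          probs = prob, na.rm = TRUE, type = 7, names = FALSE)
          v[is.na(v)] <-
            as.numeric(rstat[paste(region[panel$district[tgt]],
                                   moy[tgt])])[is.na(v)]
        }
        v
      },
      stop("unknown counterfactual rule: ", r$rule))
  }
  out
}

#' Apply a scenario's displacement rule to the flow table
#'
#' Internal (IDP/returnee) flows are filtered from `apply_from` onwards;
#' refugee flows are never touched.
#'
#' @param flows flow data.frame.
#' @param rule one of `no_drought_displacement`, `as_actual`,
#'   `no_new_displacement`.
#' @param apply_from first month the rule applies to.
#' @export
apply_displacement_rule <- function(flows, rule, apply_from = ym("2017-01")) {
  internal <- flows$kind %in% c("IDP", "returnee")
  drop <- switch(rule,
    as_actual = rep(FALSE, nrow(flows)),
    no_drought_displacement = internal & flows$reason == "drought" &
      flows$ym >= apply_from,
    no_new_displacement = internal & flows$ym >= apply_from,
    stop("unknown displacement rule: ", rule))
  flows[!drop, , drop = FALSE]
}

# Encoded district-month prediction frame + model matrix + person-time for
# a model over `months`.  `pop` is a district x month matrix already on the
# model's age scale.
prediction_design <- function(model, panel, districts, pop, months,
                              schemes = default_term_schemes()) {
  enc <- encode_world_panel(panel, districts, schemes,
                            require = model$spec$terms)
  enc <- enc[enc$ym %in% months, , drop = FALSE]
  enc$pt <- 1
  X <- design_for(model, enc)
  p <- pop[cbind(match(enc$district, rownames(pop)),
                 match(ym_format(enc$ym), colnames(pop)))]
  list(meta = data.frame(district = enc$district, ym = enc$ym,
                         stringsAsFactors = FALSE),
       X = X, person_days = p * ym_days(enc$ym), pop = p)
}

#' Predicted death tolls by district-month
#'
#' Applies a fitted mortality model to a predictor panel: the predicted
#' rate per person-day is `exp(x' beta)` and the expected toll multiplies
#' it by population person-time (`population x days in month`).
#'
#' @param model a `fitted_mortality_model`.
#' @param panel wide continuous predictor panel.
#' @param districts district table (for admin level and region).
#' @param pop district x month population matrix on the model's age scale
#'   (all-age for CDR, under-5 for U5DR), or a `population_series`.
#' @param months month indices to predict over (default: panel months
#'   intersected with the population series).
#' @param schemes term schemes.
#' @return data.frame: `district`, `ym`, `rate` (per person-day),
#'   `expected_deaths`.
#' @export
predict_tolls <- function(model, panel, districts, pop, months = NULL,
                          schemes = default_term_schemes()) {
  if (inherits(pop, "population_series"))
    pop <- if (model$spec$outcome == "U5DR") pop$pop_u5 else pop$pop
  if (is.null(months))
    months <- intersect(unique(panel$ym), ym(colnames(pop)))
  d <- prediction_design(model, panel, districts, pop, months, schemes)
  rate <- as.numeric(exp(d$X %*% model$coefficients))
  data.frame(d$meta, rate = rate, expected_deaths = rate * d$person_days,
             stringsAsFactors = FALSE)
}

# Repair a covariance matrix to PSD by clipping negative eigenvalues.
psd_repair <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= -1e-10 * max(abs(e$values), 1))) {
    if (any(e$values < 0)) {
      S <- e$vectors %*% diag(pmax(e$values, 0), nrow(S)) %*% t(e$vectors)
      attr(S, "repaired") <- TRUE
    }
    return(S)
  }
  S2 <- e$vectors %*% diag(pmax(e$values, 0), nrow(S)) %*% t(e$vectors)
  attr(S2, "repaired") <- TRUE
  S2
}

#' Bootstrap actual and counterfactual tolls from coefficient uncertainty
#'
#' Draws `B` coefficient vectors from a multivariate normal centred at the
#' robust fit (mean = point estimates, covariance = cluster-robust
#' sandwich) and, for each draw, predicts district-month deaths under the
#' actual and the counterfactual inputs with the *same* draw, so excess is
#' the within-replicate difference.  Sampling model error through the
#' coefficients (rather than adding Poisson realization noise) targets the
#' expected excess toll.
#'
#' @param model a `fitted_mortality_model`.
#' @param panel_actual,panel_cf continuous predictor panels.
#' @param pop_actual,pop_cf district x month population matrices on the
#'   model's age scale (or `population_series` objects).
#' @param districts district table.
#' @param months months the tolls accrue over.
#' @param B number of bootstrap sets (>= 100; default 10,000).
#' @param seed integer seed.
#' @param schemes term schemes.
#' @return object of class `excess_bootstrap`: `meta` (district, ym, and
#'   derived year/region), matrices `actual` and `excess`
#'   (district-month x replicate).
#' @export
bootstrap_excess <- function(model, panel_actual, pop_actual, panel_cf,
                             pop_cf, districts, months, B = 10000L,
                             seed = 1L, schemes = default_term_schemes()) {
  if (B < 100L) stop("need at least 100 bootstrap sets")
  take_pop <- function(pop) {
    if (inherits(pop, "population_series"))
      pop <- if (model$spec$outcome == "U5DR") pop$pop_u5 else pop$pop
    pop
  }
  da <- prediction_design(model, panel_actual, districts, take_pop(pop_actual),
                          months, schemes)
  dc <- prediction_design(model, panel_cf, districts, take_pop(pop_cf),
                          months, schemes)
  stopifnot(identical(da$meta$district, dc$meta$district),
            identical(da$meta$ym, dc$meta$ym))
  S <- psd_repair(model$vcov)
  betas <- with_seed(seed,
    MASS::mvrnorm(B, mu = model$coefficients, Sigma = S))
  if (B == 1L) betas <- matrix(betas, nrow = 1L)
  act <- exp(da$X %*% t(betas)) * da$person_days
  cf <- exp(dc$X %*% t(betas)) * dc$person_days
  meta <- da$meta
  meta$year <- ym_year(meta$ym)
  meta$region <- districts$region[match(meta$district, districts$district)]
  structure(list(meta = meta, actual = act, excess = act - cf,
                 person_days = da$person_days,
                 outcome = model$spec$outcome,
                 repaired = isTRUE(attr(S, "repaired"))),
            class = "excess_bootstrap")
}

# Histogram mode: Freedman-Diaconis bins, midpoint of the modal bin.
mode_estimate <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Summarise bootstrap replicates by stratum
#'
#' Sums the per-replicate district-month values within each stratum (so
#' district excesses add exactly to the national excess within every
#' replicate), then reports the histogram mode and the empirical
#' `alpha/2`-`1 - alpha/2` percentile interval (type-7 quantiles) per
#' stratum.
#'
#' @param boot an `excess_bootstrap`.
#' @param by stratification: `"overall"`, `"year"`, `"region"`,
#'   `"district"`, `"month"`, or `"region_year"`.
#' @param what `"excess"` or `"actual"` tolls.
#' @param alpha interval tail mass (default 0.05).
#' @return data.frame: stratum columns, `mode`, `mean`, `lci`, `uci`.
#' @export
summarize_excess <- function(boot, by = "overall", what = "excess",
                             alpha = 0.05) {
  stopifnot(inherits(boot, "excess_bootstrap"))
  M <- boot[[what]]
  if (ncol(M) < 100L) warning("fewer than 100 replicates")
  g <- switch(by,
    overall = rep("overall", nrow(M)),
    year = as.character(boot$meta$year),
    region = boot$meta$region,
    district = boot$meta$district,
    month = ym_format(boot$meta$ym),
    region_year = paste(boot$meta$region, boot$meta$year, sep = ":"),
    stop("unknown stratification: ", by))
  agg <- rowsum(M, g)   # strata x replicates
  q <- t(apply(agg, 1L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
               type = 7, names = FALSE))
  data.frame(stratum = rownames(agg),
             mode = apply(agg, 1L, mode_estimate),
             mean = rowMeans(agg), lci = q[, 1L], uci = q[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Report tables of total and excess deaths
#'
#' Assembles the year-by-scenario table (total deaths plus excess deaths
#' under each counterfactual scenario, with an overall row) and the
#' by-region table (death rate per 10,000 person-days, excess rate and
#' excess toll) for one age group, rounding tolls to the nearest 100
#' (half up).
#'
#' @param boots named list of `excess_bootstrap` objects, one per scenario;
#'   actual tolls are taken from the first.
#' @param alpha interval tail mass.
#' @return list with data.frames `by_year` and `by_region`.
#' @export
aggregate_tables <- function(boots, alpha = 0.05) {
  stopifnot(length(boots) >= 1L, !is.null(names(boots)))
  r100 <- function(x) round_half_up(x, 100)
  fmt <- function(s) data.frame(
    stratum = s$stratum, estimate = r100(s$mode),
    lci = r100(s$lci), uci = r100(s$uci), stringsAsFactors = FALSE)

  tot_y <- summarize_excess(boots[[1L]], "year", "actual", alpha)
  tot_o <- summarize_excess(boots[[1L]], "overall", "actual", alpha)
  by_year <- data.frame(period = c(tot_y$stratum, "overall"),
                        rbind(fmt(tot_y)[-1L], fmt(tot_o)[-1L]),
                        stringsAsFactors = FALSE)
  names(by_year)[-1L] <- paste0("total_", c("deaths", "lci", "uci"))
  for (sc in names(boots)) {
    ex_y <- summarize_excess(boots[[sc]], "year", "excess", alpha)
    ex_o <- summarize_excess(boots[[sc]], "overall", "excess", alpha)
    add <- rbind(fmt(ex_y)[-1L], fmt(ex_o)[-1L])
    names(add) <- paste0("excess_", sc, c("", "_lci", "_uci"))
    by_year <- cbind(by_year, add)
  }

  b1 <- boots[[1L]]
  pd_region <- tapply(b1$person_days, b1$meta$region, sum)
  reg_tot <- summarize_excess(b1, "region", "actual", alpha)
  by_region <- data.frame(
    region = reg_tot$stratum,
    death_rate = 1e4 * reg_tot$mode / pd_region[reg_tot$stratum],
    death_rate_lci = 1e4 * reg_tot$lci / pd_region[reg_tot$stratum],
    death_rate_uci = 1e4 * reg_tot$uci / pd_region[reg_tot$stratum],
    row.names = NULL, stringsAsFactors = FALSE)
  for (sc in names(boots)) {
    ex_r <- summarize_excess(boots[[sc]], "region", "excess", alpha)
    i <- match(by_region$region, ex_r$stratum)
    by_region[[paste0("excess_rate_", sc)]] <-
      1e4 * ex_r$mode[i] / pd_region[by_region$region]
    by_region[[paste0("excess_", sc)]] <- r100(ex_r$mode[i])
    by_region[[paste0("excess_", sc, "_lci")]] <- r100(ex_r$lci[i])
    by_region[[paste0("excess_", sc, "_uci")]] <- r100(ex_r$uci[i])
  }
  list(by_year = by_year, by_region = by_region)
}
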