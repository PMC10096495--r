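#' Analysis configuration
#'
#' Bundles every tunable the pipeline uses. Defaults: 2.1%/yr population
#' growth, 25.0% under-5 fraction, spatial imputation weights 1 and 0.3, spline
#' smoothness 0.3, completeness thresholds 0.70/0.70, lags up to 6 months,
#' 10-fold cross-validation, 80% training share, top-20% shortlist, 10,000
#' bootstrap sets, and 95% intervals.
#'
#' @param month_range inclusive `"YYYY-MM"` analysis endpoints.
#' @param excess_years calendar years excess mortality accrues over.
#' @param reference_years pre-crisis reference years for counterfactuals.
#' @param apply_from first month counterfactual rules apply to.
#' @param growth_rate_yr,under5_fraction demographic constants.
#' @param w_in,w_out spatial imputation weights.
#' @param smoothness spline smoothing knob.
#' @param cell_threshold,coverage_threshold completeness rule.
#' @param max_lag maximum predictor lag in months.
#' @param cv_folds cross-validation folds.
#' @param train_frac holdout training share.
#' @param shortlist_frac shortlist fraction of the ranked search.
#' @param max_terms largest model searched.
#' @param search_cap maximum subsets enumerated.
#' @param B bootstrap sets.
#' @param alpha interval tail mass.
#' @param scenarios scenario names to run.
#' @param n_surveys,individual_frac synthetic-survey settings (simulate
#'   mode).
#' @param seed master seed; stage seeds derive from it via [stage_seed()].
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(month_range = c("2014-01", "2018-12"),
                            excess_years = 2017:2018,
                            reference_years = 2014:2016,
                            apply_from = "2017-01",
                            growth_rate_yr = 0.021,
                            under5_fraction = 0.250,
                            w_in = 1.0, w_out = 0.3,
                            smoothness = 0.3,
                            cell_threshold = 0.70, coverage_threshold = 0.70,
                            max_lag = 6L,
                            cv_folds = 10L, train_frac = 0.8,
                            shortlist_frac = 0.2,
                            max_terms = 6L, search_cap = 1024L,
                            B = 10000L, alpha = 0.05,
                            scenarios = c("most_likely", "worst_case",
                                          "best_case"),
                            n_surveys = 60L, individual_frac = 0.7,
                            seed = 1L) {
  months <- ym_seq(month_range[1], month_range[2])
  structure(list(
    month_range = months[c(1L, length(months))],
    excess_years = as.integer(excess_years),
    excess_months = months[ym_year(months) %in% excess_years],
    reference_years = as.integer(reference_years),
    apply_from = ym(apply_from),
    growth_rate_yr = growth_rate_yr, under5_fraction = under5_fraction,
    w_in = w_in, w_out = w_out, smoothness = smoothness,
    cell_threshold = cell_threshold, coverage_threshold = coverage_threshold,
    max_lag = as.integer(max_lag), cv_folds = as.integer(cv_folds),
    train_frac = train_frac, shortlist_frac = shortlist_frac,
    max_terms = as.integer(max_terms), search_cap = as.integer(search_cap),
    B = as.integer(B), alpha = alpha, scenarios = scenarios,
    n_surveys = as.integer(n_surveys), individual_frac = individual_frac,
    seed = as.integer(seed)), class = "analysis_config")
}

#' Excess bootstrap for one scenario from raw inputs
#'
#' Convenience wrapper tying the stages together for a single scenario:
#' rebuilds actual and counterfactual population series from the census
#' anchors and (rule-filtered) flows, builds the counterfactual predictor
#' panel, and runs [bootstrap_excess()] over the configured excess months.
#'
#' @param model a `fitted_mortality_model`.
#' @param panel continuous predictor panel.
#' @param districts district table.
#' @param anchors list of [census_anchor()]s.
#' @param flows flow data.frame.
#' @param scenario a [scenario_spec()].
#' @param config an [analysis_config()].
#' @param B,seed bootstrap settings.
#' @return an `excess_bootstrap`.
#' @export
excess_for_inputs <- function(model, panel, districts, anchors, flows,
                              scenario, config, B = config$B, seed = 1L) {
  flows_cf <- apply_displacement_rule(flows, scenario$displacement,
                                      config$apply_from)
  pop_act <- build_population_series(anchors, flows, config$month_range,
                                     config$growth_rate_yr,
                                     config$under5_fraction)
  pop_cf <- build_population_series(anchors, flows_cf, config$month_range,
                                    config$growth_rate_yr,
                                    config$under5_fraction)
  panel_cf <- build_counterfactual(panel, scenario, config$reference_years,
                                   config$apply_from)
  bootstrap_excess(model, panel, pop_act, panel_cf, pop_cf, districts,
                   config$excess_months, B = B, seed = seed)
}

#' Run the full estimation pipeline
#'
#' Executes the six stages in order: survey re-analysis, population
#' denominators, predictor panel preparation, predictive model selection,
#' and counterfactual excess estimation (sensitivity analyses are separate,
#' see [run_bias_grid()] and [reattribute_and_rerun()]).  Inputs are either
#' a synthetic world simulated here (default), or pre-built objects passed
#' in.  Every stage's randomness derives from the master seed, so a re-run
#' with the same config reproduces every output.
#'
#' @param config an [analysis_config()].
#' @param world optional `synthetic_world` (default: simulated from the
#'   config with the derived stage seed).
#' @param surveys optional list of [survey_dataset()]s.
#' @param output_dir optional directory; when given, stage outputs and a
#'   run manifest are written as CSV/JSON.
#' @return pipeline state: a list with the inputs, per-survey estimates,
#'   population series, panel, leaderboard, fitted models, per-scenario
#'   bootstraps, report tables and manifest.
#' @export
run_all <- function(config = analysis_config(), world = NULL, surveys = NULL,
                    output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))

  # -- stage 0: inputs -----------------------------------------------------
  if (is.null(world)) {
    wc <- world_config(month_range = ym_format(config$month_range),
                       growth_rate_yr = config$growth_rate_yr,
                       under5_fraction = config$under5_fraction,
                       seed = stage_seed(config$seed, "simulate"))
    world <- generate_world(wc)
  }
  if (is.null(surveys)) {
    n_ind <- round(config$individual_frac * config$n_surveys)
    surveys <- c(
      generate_surveys(world, n_ind, questionnaire = "individual",
                       seed = stage_seed(config$seed, "surveys_individual")),
      if (config$n_surveys - n_ind > 0)
        generate_surveys(world, config$n_surveys - n_ind,
                         questionnaire = "aggregate",
                         seed = stage_seed(config$seed, "surveys_aggregate")))
    for (i in seq_along(surveys))
      surveys[[i]]$meta$survey_id <- sprintf("svy%03d", i)
  }

  # -- stage 1: survey re-analysis ----------------------------------------
  elig <- filter_eligible(surveys, min_year = ym_year(config$month_range[1]))
  estimates <- survey_estimates_table(elig$eligible)

  # -- stage 2: population denominators -----------------------------------
  pop_act <- build_population_series(world$anchors, world$flows,
                                     config$month_range,
                                     config$growth_rate_yr,
                                     config$under5_fraction)
  displacement <- displacement_summary(world$flows)

  # -- stage 3: predictor panel -------------------------------------------
  value_cols <- setdiff(names(world$predictors), c("district", "ym"))
  raw <- do.call(rbind, lapply(value_cols, function(p)
    data.frame(district = world$predictors$district,
               ym = world$predictors$ym, predictor = p,
               value = world$predictors[[p]], stringsAsFactors = FALSE)))
  region <- stats::setNames(world$districts$region, world$districts$district)
  prep <- prepare_panel(raw, region, smooth = "water_price",
                        smoothness = config$smoothness,
                        w_in = config$w_in, w_out = config$w_out,
                        cell_threshold = config$cell_threshold,
                        coverage_threshold = config$coverage_threshold)
  panel <- prep$panel

  # -- stage 4: model selection -------------------------------------------
  model_data <- survey_model_data(elig$eligible, panel, world$districts)
  candidates <- intersect(names(default_term_schemes()), names(panel))
  candidates <- union("admin_level", candidates)
  screen_seed <- stage_seed(config$seed, "model_selection")
  screened <- screen_predictors(candidates, model_data, "CDR",
                                k = config$cv_folds, seed = screen_seed)
  leaderboard <- brute_force_search(screened, model_data, "CDR",
                                    max_terms = config$max_terms,
                                    k = config$cv_folds, seed = screen_seed,
                                    cap = config$search_cap)
  short <- shortlist(leaderboard, config$shortlist_frac)
  final_spec <- select_model(short, model_data, config$train_frac,
                             seed = screen_seed)
  model_cdr <- fit_quasipoisson(model_data, final_spec)
  # the same specification is used for the under-5 outcome
  model_u5dr <- fit_quasipoisson(model_data,
                                 model_spec("U5DR", final_spec$terms))

  # -- stage 5: excess mortality ------------------------------------------
  boots <- list(CDR = list(), U5DR = list())
  for (sc in config$scenarios) {
    boot_seed <- stage_seed(config$seed, paste0("excess_", sc))
    boots$CDR[[sc]] <- excess_for_inputs(model_cdr, panel, world$districts,
                                         world$anchors, world$flows,
                                         scenario_spec(sc), config,
                                         seed = boot_seed)
    boots$U5DR[[sc]] <- excess_for_inputs(model_u5dr, panel, world$districts,
                                          world$anchors, world$flows,
                                          scenario_spec(sc), config,
                                          seed = boot_seed)
  }
  tables <- list(all_ages = aggregate_tables(boots$CDR, config$alpha),
                 under5 = aggregate_tables(boots$U5DR, config$alpha))

  manifest <- list(
    package_version = as.character(utils::packageVersion("crisismort")),
    config_hash = config_hash(config),
    master_seed = config$seed,
    stage_seeds = list(
      simulate = stage_seed(config$seed, "simulate"),
      surveys_individual = stage_seed(config$seed, "surveys_individual"),
      surveys_aggregate = stage_seed(config$seed, "surveys_aggregate"),
      model_selection = screen_seed,
      excess = lapply(stats::setNames(config$scenarios, config$scenarios),
                      function(sc) stage_seed(config$seed, paste0("excess_", sc)))),
    design_flags = list(
      sandwich = "CR0 clustered on survey cluster",
      cv_unit = "survey",
      dss_variance = "dispersion * mu",
      bootstrap_error = "coefficient uncertainty only (multivariate normal)",
      mode = "Freedman-Diaconis histogram midpoint",
      percentile = "type 7 (linear interpolation)",
      final_model_rule = attr(final_spec, "rule")),
    selected_terms = final_spec$terms,
    n_surveys_modelled = length(elig$eligible),
    exclusions = table(elig$exclusions$reason))

  state <- list(config = config, world = world, surveys = surveys,
                eligible = elig$eligible, exclusions = elig$exclusions,
                estimates = estimates, pop_act = pop_act,
                displacement = displacement, panel = panel,
                provenance = prep$provenance, model_data = model_data,
                screened = screened, leaderboard = leaderboard,
                shortlist = short, model_cdr = model_cdr,
                model_u5dr = model_u5dr, boots = boots, tables = tables,
                districts = world$districts, anchors = world$anchors,
                flows = world$flows, manifest = manifest)
  if (!is.null(output_dir)) write_pipeline_outputs(state, output_dir)
  invisible(state)
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

write_pipeline_outputs <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(state$estimates, "survey_estimates.csv")
  w(state$exclusions, "survey_exclusions.csv")
  w(as.data.frame(state$pop_act), "population.csv")
  w(state$displacement, "displacement_summary.csv")
  pw <- state$panel; pw$month <- ym_format(pw$ym)
  w(pw, "predictor_panel.csv")
  w(state$provenance, "predictor_provenance.csv")
  w(state$leaderboard, "model_leaderboard.csv")
  stab <- attr(state$model_cdr$spec, "table")
  if (is.null(stab)) stab <- as.data.frame(state$shortlist)
  w(stab, "model_shortlist.csv")
  for (ag in names(state$tables)) {
    w(state$tables[[ag]]$by_year, paste0("excess_by_year_", ag, ".csv"))
    w(state$tables[[ag]]$by_region, paste0("excess_by_region_", ag, ".csv"))
  }
  model_json <- list(
    CDR = list(terms = state$model_cdr$spec$terms,
               coefficients = as.list(state$model_cdr$coefficients),
               dispersion = state$model_cdr$dispersion,
               vcov = state$model_cdr$vcov),
    U5DR = list(terms = state$model_u5dr$spec$terms,
                coefficients = as.list(state$model_u5dr$coefficients),
                dispersion = state$model_u5dr$dispersion,
                vcov = state$model_u5dr$vcov))
  jsonlite::write_json(model_json, file.path(dir, "fitted_models.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(state$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
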