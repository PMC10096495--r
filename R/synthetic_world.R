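#' Configuration for a synthetic crisis world
#'
#' Defines the ground truth from which every downstream input (predictor
#' panels, census anchors, displacement flows, household surveys) is
#' simulated.  District-month log death rates follow
#' `log(baseline) + sum(coefficient * term)`, with terms encoded exactly as
#' the modelling stage encodes them (same category cut-points and lags), so
#' model fitting has a well-defined estimand.
#'
#' Defaults emulate the study conditions of a two-year drought-triggered
#' crisis overlaid on a stable baseline: baseline crude death rate 0.43 and
#' under-5 death rate 0.66 per 10,000 person-days (typical survey medians in
#' this setting), 2.1%/yr natural growth, 25.0% of the population under 5,
#' and a crisis window (elevated conflict, SAM admissions and measles, and
#' depressed malaria) spanning January 2017 to December 2018.
#'
#' @param n_districts number of districts (>= 2).
#' @param n_regions number of regions districts nest in.
#' @param month_range inclusive `"YYYY-MM"` endpoints of the analysis period
#'   (length >= 24 so a pre-crisis reference window exists).
#' @param true_coefficients term -> named log-rate-ratio vector, as in
#'   [default_true_coefficients()].
#' @param baseline_cdr,baseline_u5dr reference-level death rates per 10,000
#'   person-days (all-age / under-5).
#' @param growth_rate_yr natural yearly population growth (proportion).
#' @param under5_fraction proportion of the population under 5 years.
#' @param crisis_window `"YYYY-MM"` endpoints of the crisis period.
#' @param schemes term schemes ([default_term_schemes()]).
#' @param seed integer seed; the world is a pure function of the config.
#' @return object of class `world_config`.
#' @export
world_config <- function(n_districts = 20L,
                         n_regions = 5L,
                         month_range = c("2014-01", "2018-12"),
                         true_coefficients = default_true_coefficients(),
                         baseline_cdr = 0.43,
                         baseline_u5dr = 0.66,
                         growth_rate_yr = 0.021,
                         under5_fraction = 0.250,
                         crisis_window = c("2017-01", "2018-12"),
                         schemes = default_term_schemes(),
                         seed = 1L) {
  months <- ym_seq(month_range[1], month_range[2])
  if (n_districts < 2L) stop("need at least 2 districts")
  if (length(months) < 24L) stop("month range must span at least 24 months")
  if (baseline_cdr <= 0 || baseline_u5dr <= 0) stop("baseline rates must be positive")
  if (under5_fraction <= 0 || under5_fraction >= 1)
    stop("under5_fraction must lie in (0, 1)")
  for (nm in names(true_coefficients)) {
    defn <- schemes[[nm]]
    if (is.null(defn))
      stop("coefficient references unknown predictor term: ", nm)
    lev <- if (defn$type == "factor") defn$levels else defn$scheme$labels
    bad <- setdiff(names(true_coefficients[[nm]]), lev)
    if (length(bad))
      stop("coefficient for term '", nm, "' references unknown level: ",
           paste(bad, collapse = ", "))
  }
  structure(list(
    n_districts = as.integer(n_districts), n_regions = as.integer(n_regions),
    month_range = months[c(1L, length(months))],
    true_coefficients = true_coefficients,
    baseline_cdr = baseline_cdr, baseline_u5dr = baseline_u5dr,
    growth_rate_yr = growth_rate_yr, under5_fraction = under5_fraction,
    crisis_window = c(ym(crisis_window[1]), ym(crisis_window[2])),
    schemes = schemes, seed = as.integer(seed)
  ), class = "world_config")
}

# Replay recorded flows over anchor populations: P[t+1] = g * P[t] + net[t+1],
# flooring at `floor`.  `flows` rows outside `months` are ignored.  Used both
# when generating the world and when rebuilding truth under counterfactual
# displacement rules.
evolve_population <- function(base_pop, months, growth_rate_yr, flows,
                              floor = 1) {
  g <- (1 + growth_rate_yr)^(1 / 12)
  districts <- names(base_pop)
  pop <- matrix(NA_real_, nrow = length(districts), ncol = length(months),
                dimnames = list(districts, ym_format(months)))
  pop[, 1L] <- base_pop
  net <- net_flow_matrix(districts, months, flows)
  for (j in seq_along(months)[-1L]) {
    pop[, j] <- pmax(floor, g * pop[, j - 1L] + net[, j])
  }
  pop
}

# district x month net flow matrix (inflow - outflow); NA origin/destination
# marks cross-border legs.
net_flow_matrix <- function(districts, months, flows) {
  net <- matrix(0, nrow = length(districts), ncol = length(months),
                dimnames = list(districts, ym_format(months)))
  if (is.null(flows) || nrow(flows) == 0L) return(net)
  f <- flows[flows$ym %in% months, , drop = FALSE]
  if (nrow(f) == 0L) return(net)
  jcol <- match(f$ym, months)
  out_i <- match(f$origin, districts)
  in_i <- match(f$destination, districts)
  for (k in seq_len(nrow(f))) {
    if (!is.na(out_i[k])) net[out_i[k], jcol[k]] <- net[out_i[k], jcol[k]] - f$persons[k]
    if (!is.na(in_i[k])) net[in_i[k], jcol[k]] <- net[in_i[k], jcol[k]] + f$persons[k]
  }
  net
}

#' Generate a synthetic world
#'
#' Simulates districts, a continuous predictor panel (conflict, SAM
#' admission, malaria and measles incidence rates per 100,000 person-months,
#' plus nuisance water-price and rainfall series), true populations evolved
#' under natural growth and reason-tagged displacement flows, discrepant
#' census-source anchors, and the implied true district-month log death
#' rates.
#'
#' @param config a [world_config()].
#' @return object of class `synthetic_world` with elements `districts`,
#'   `predictors` (continuous truth panel, starts 6 months before the
#'   analysis range so lags are always defined), `truth` (district-month
#'   population and true log rates), `anchors`, `flows`, and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  nd <- config$n_districts
  districts_id <- sprintf("d%02d", seq_len(nd))
  region_id <- sprintf("r%02d", rep_len(seq_len(config$n_regions), nd))
  # northern regions (stable admin) vs south-central
  n_north <- max(1L, floor(config$n_regions * 0.4))
  admin <- ifelse(as.integer(sub("r", "", region_id)) <= n_north,
                  "somaliland_puntland", "south_central")
  livelihood <- sample(c("pastoral", "agropastoral", "riverine", "urban"),
                       nd, replace = TRUE, prob = c(0.4, 0.3, 0.1, 0.2))
  districts <- data.frame(district = districts_id, region = region_id,
                          admin_level = admin, livelihood = livelihood,
                          stringsAsFactors = FALSE)

  a_months <- ym_seq(config$month_range[1], config$month_range[2])
  p_months <- ym_seq(config$month_range[1] - 6L, config$month_range[2])
  np <- length(p_months)
  crisis <- p_months >= config$crisis_window[1] & p_months <= config$crisis_window[2]
  moy <- ym_month(p_months)

  # --- continuous predictor truth (rates per 100,000 person-months) -------
  grid <- expand.grid(district = districts_id, ym = p_months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cr <- crisis[match(grid$ym, p_months)]
  base_conflict <- stats::setNames(exp(stats::rnorm(nd, log(0.12), 0.7)), districts_id)
  base_conflict[admin == "south_central"] <- base_conflict[admin == "south_central"] * 2.2
  base_sam <- stats::setNames(exp(stats::rnorm(nd, log(70), 0.4)), districts_id)
  malaria_present <- stats::setNames(stats::runif(nd) < 0.8, districts_id)
  base_malaria <- stats::setNames(exp(stats::rnorm(nd, log(45), 0.9)), districts_id)

  conflict <- base_conflict[grid$district] *
    ifelse(cr, 3.0, 1.0) * exp(stats::rnorm(nrow(grid), 0, 0.35))
  season <- 1 + 0.25 * sin(2 * pi * moy[match(grid$ym, p_months)] / 12)
  sam <- base_sam[grid$district] * season *
    ifelse(cr, 2.8, 1.0) * exp(stats::rnorm(nrow(grid), 0, 0.25))
  malaria <- ifelse(malaria_present[grid$district],
                    base_malaria[grid$district] * season *
                      ifelse(cr, 0.45, 1.0) *
                      exp(stats::rnorm(nrow(grid), 0, 0.35)),
                    0)
  outbreak <- stats::runif(nrow(grid)) < ifelse(cr, 0.45, 0.08)
  measles <- ifelse(outbreak, exp(stats::rnorm(nrow(grid), log(15), 0.7)), 0)
  water_price <- 10000 * exp(stats::rnorm(nrow(grid), 0, 0.15)) *
    ifelse(cr, 1.4, 1.0)
  rainfall <- pmax(0, 60 * (1 + sin(2 * pi * moy[match(grid$ym, p_months)] / 6)) *
                     ifelse(cr, 0.5, 1.0) + stats::rnorm(nrow(grid), 0, 15))

  predictors <- data.frame(grid, conflict = conflict, sam = sam,
                           malaria = malaria, measles = measles,
                           water_price = water_price, rainfall = rainfall,
                           stringsAsFactors = FALSE)
  predictors <- predictors[order(predictors$district, predictors$ym), ]
  rownames(predictors) <- NULL

  # --- populations and displacement flows --------------------------------
  base_pop <- stats::setNames(round(exp(stats::rnorm(nd, log(180000), 0.45))),
                              districts_id)
  g <- (1 + config$growth_rate_yr)^(1 / 12)
  flow_start <- max(a_months[1], ym(sprintf("%04d-01", ym_year(a_months[1]) + 2)))
  pop <- matrix(NA_real_, nd, length(a_months),
                dimnames = list(districts_id, ym_format(a_months)))
  pop[, 1L] <- base_pop
  idp <- base_pop * 0.08
  prop_idp <- matrix(NA_real_, nd, length(a_months),
                     dimnames = dimnames(pop))
  prop_idp[, 1L] <- 0.08
  flows_list <- list()
  for (j in seq_along(a_months)[-1L]) {
    m <- a_months[j]
    cur <- g * pop[, j - 1L]
    if (m >= flow_start) {
      in_crisis <- m >= config$crisis_window[1] && m <= config$crisis_window[2]
      out_rate <- if (in_crisis) 0.008 else 0.0015
      n_out <- pmin(stats::rbinom(nd, size = round(cur), prob = out_rate),
                    round(0.05 * cur))
      dest <- vapply(seq_len(nd), function(i) {
        w <- cur; w[i] <- 0
        sample(districts_id, 1L, prob = w)
      }, "")
      # reason mix chosen so the 2016-18 aggregate lands near the reported
      # drought/insecurity/flooding/other split of roughly 54/30/13/3
      reason_p <- if (in_crisis) c(0.59, 0.27, 0.11, 0.03) else c(0.05, 0.55, 0.25, 0.15)
      reason <- sample(c("drought", "insecurity", "flooding", "other"),
                       nd, replace = TRUE, prob = reason_p)
      kind <- sample(c("IDP", "returnee"), nd, replace = TRUE, prob = c(0.85, 0.15))
      keep <- n_out > 0
      if (any(keep)) {
        fl <- data.frame(ym = m, origin = districts_id[keep],
                         destination = dest[keep], persons = n_out[keep],
                         reason = reason[keep], kind = kind[keep],
                         stringsAsFactors = FALSE)
        # small refugee out-flow across the border (no internal destination)
        n_ref <- stats::rbinom(nd, size = round(cur), prob = 0.0002)
        if (any(n_ref > 0)) {
          fl <- rbind(fl, data.frame(
            ym = m, origin = districts_id[n_ref > 0], destination = NA_character_,
            persons = n_ref[n_ref > 0], reason = "other", kind = "refugee",
            stringsAsFactors = FALSE))
        }
        flows_list[[length(flows_list) + 1L]] <- fl
        net <- net_flow_matrix(districts_id, m, fl)[, 1L]
        cur <- pmax(1, cur + net)
        inflow <- tapply(fl$persons[!is.na(fl$destination) & fl$kind != "refugee"],
                         fl$destination[!is.na(fl$destination) & fl$kind != "refugee"],
                         sum)
        idp[names(inflow)] <- idp[names(inflow)] + inflow
      }
    }
    pop[, j] <- cur
    prop_idp[, j] <- pmin(0.95, idp / cur)
  }
  flows <- if (length(flows_list)) do.call(rbind, flows_list) else
    data.frame(ym = integer(), origin = character(), destination = character(),
               persons = numeric(), reason = character(), kind = character(),
               stringsAsFactors = FALSE)

  # --- census anchors with per-source multiplicative bias -----------------
  src <- data.frame(
    source = c("demographic_survey", "remote_sensing", "campaign_enumeration",
               "immunization_program"),
    ym = c(a_months[3], a_months[13], a_months[length(a_months) - 1L],
           a_months[length(a_months)]),
    quality = c(0.7, 0.5, 0.4, 0.3), stringsAsFactors = FALSE)
  anchors <- lapply(seq_len(nrow(src)), function(i) {
    bias <- stats::runif(1, 0.85, 1.15)
    census_anchor(source = src$source[i], ym = src$ym[i],
                  population = round(pop[, ym_format(src$ym[i])] * bias),
                  quality = src$quality[i], bias = bias)
  })

  # --- true log death rates ----------------------------------------------
  enc <- encode_world_panel(predictors, districts, config$schemes)
  lp <- linpred_terms(enc, config$true_coefficients)
  truth <- data.frame(district = enc$district, ym = enc$ym,
                      log_cdr = log(config$baseline_cdr) + lp,
                      log_u5dr = log(config$baseline_u5dr) + lp,
                      stringsAsFactors = FALSE)
  truth <- truth[truth$ym %in% a_months, ]
  key <- paste(truth$district, truth$ym)
  pkey <- paste(rep(districts_id, times = length(a_months)),
                rep(a_months, each = nd))
  truth$pop <- as.vector(pop)[match(key, pkey)]
  truth$pop_u5 <- truth$pop * config$under5_fraction
  truth$prop_idp <- as.vector(prop_idp)[match(key, pkey)]
  rownames(truth) <- NULL

  structure(list(config = config, districts = districts,
                 predictors = predictors, truth = truth,
                 anchors = anchors, flows = flows,
                 base_pop = base_pop, months = a_months),
            class = "synthetic_world")
}

# Lag + categorize the continuous panel into model term columns.  Rows are
# kept when complete for the terms in `require` (default: every scheme
# term present), so e.g. an intercept-only prediction is not blocked by an
# unavailable lag of an unused predictor.
encode_world_panel <- function(predictors, districts, schemes,
                               require = names(schemes)) {
  df <- predictors
  for (nm in names(schemes)) {
    defn <- schemes[[nm]]
    if (defn$type != "categorical" || !nm %in% names(df)) next
    k <- defn$scheme$lag
    if (k > 0L) {
      key <- paste(df$district, df$ym - k)
      df[[nm]] <- df[[nm]][match(key, paste(df$district, df$ym))]
    }
  }
  df$admin_level <- districts$admin_level[match(df$district, districts$district)]
  need <- intersect(intersect(names(schemes), require), names(df))
  keep <- if (length(need)) stats::complete.cases(df[need]) else
    rep(TRUE, nrow(df))
  encode_terms(df[keep, , drop = FALSE], schemes)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world>", x$config$n_districts, "districts,",
      length(x$months), "months (", ym_format(x$months[1]), "to",
      ym_format(x$months[length(x$months)]), ")\n")
  cat("  flows:", nrow(x$flows), "rows; anchors:", length(x$anchors),
      "census sources\n")
  invisible(x)
}

#' True excess deaths implied by a synthetic world
#'
#' Computes, from the generator's own truth (true coefficients, true
#' populations), the expected death toll under actual conditions and under a
#' counterfactual scenario, over `period_years`.  This is the ground truth
#' that interval estimates from the fitted pipeline are judged against.
#'
#' @param world a `synthetic_world`.
#' @param scenario a [scenario_spec()] (default most-likely).
#' @param period_years calendar years the excess accrues over (default: the
#'   crisis window's years).
#' @param outcome `"CDR"` or `"U5DR"`.
#' @return list with `actual`, `counterfactual` and `excess` expected deaths.
#' @export
true_excess <- function(world, scenario = scenario_spec("most_likely"),
                        period_years = NULL, outcome = "CDR") {
  cfg <- world$config
  if (is.null(period_years))
    period_years <- unique(ym_year(seq.int(cfg$crisis_window[1], cfg$crisis_window[2])))
  ref_years <- reference_years_for(world)
  panel_cf <- build_counterfactual(world$predictors, scenario,
                                   reference_years = ref_years,
                                   apply_from = min(cfg$crisis_window))
  flows_cf <- apply_displacement_rule(world$flows, scenario$displacement,
                                      apply_from = min(cfg$crisis_window))
  pop_cf <- evolve_population(world$base_pop, world$months,
                              cfg$growth_rate_yr, flows_cf)
  months <- world$months[ym_year(world$months) %in% period_years]

  toll <- function(panel, popm) {
    enc <- encode_world_panel(panel, world$districts, cfg$schemes)
    lp <- linpred_terms(enc, cfg$true_coefficients)
    base <- if (outcome == "CDR") cfg$baseline_cdr else cfg$baseline_u5dr
    rate <- base / 1e4 * exp(lp)
    keep <- enc$ym %in% months
    p <- popm[cbind(match(enc$district[keep], rownames(popm)),
                    match(ym_format(enc$ym[keep]), colnames(popm)))]
    if (outcome == "U5DR") p <- p * cfg$under5_fraction
    sum(rate[keep] * p * ym_days(enc$ym[keep]))
  }
  dd <- sort(unique(world$truth$district))
  pop_act <- matrix(NA_real_, length(dd), length(world$months),
                    dimnames = list(dd, ym_format(world$months)))
  pop_act[cbind(match(world$truth$district, dd),
                match(world$truth$ym, world$months))] <- world$truth$pop
  actual <- toll(world$predictors, pop_act)
  counterfactual <- toll(panel_cf, pop_cf)
  list(actual = actual, counterfactual = counterfactual,
       excess = actual - counterfactual)
}

# Reference years: the pre-crisis years of the analysis range.
reference_years_for <- function(world) {
  yrs <- unique(ym_year(world$months))
  crisis_start <- ym_year(world$config$crisis_window[1])
  yrs[yrs < crisis_start]
}
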