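#' Survey metadata
#'
#' @param survey_id survey identifier.
#' @param district district surveyed.
#' @param universe sampling universe (`"district"`, `"urban"`,
#'   `"idp_settlement"`, or `"livelihood_zone"` — the latter is ineligible
#'   for district-level modelling).
#' @param design `"cluster"` (two-stage cluster sample) or `"systematic"`.
#' @param recall_start,recall_end recall period endpoints (`Date`).
#' @param questionnaire `"individual"` (member-listing) or `"aggregate"`
#'   (household totals and event counts only).
#' @param frame_clear,standard_questionnaire logical metadata flags used by
#'   eligibility filtering.
#' @param quality_score survey quality in `[0, 1]` (NA until scored).
#' @return object of class `survey_meta`.
#' @export
survey_meta <- function(survey_id, district, universe = "district",
                        design = "cluster", recall_start, recall_end,
                        questionnaire = "individual", frame_clear = TRUE,
                        standard_questionnaire = TRUE, quality_score = NA_real_) {
  recall_start <- as.Date(recall_start); recall_end <- as.Date(recall_end)
  if (!is.na(recall_start) && !is.na(recall_end) && recall_end <= recall_start)
    stop("recall end must be after recall start")
  if (!is.na(quality_score) && (quality_score < 0 || quality_score > 1))
    stop("quality score must lie in [0, 1]")
  structure(list(survey_id = survey_id, district = district,
                 universe = universe, design = design,
                 recall_start = recall_start, recall_end = recall_end,
                 questionnaire = questionnaire, frame_clear = frame_clear,
                 standard_questionnaire = standard_questionnaire,
                 quality_score = quality_score),
            class = "survey_meta")
}

#' A retrospective mortality survey dataset
#'
#' Individual-questionnaire surveys carry a member listing (`members`);
#' aggregate-questionnaire surveys carry only household totals and event
#' counts (`households`).  [survey_households()] converts either into the
#' canonical household person-time table.
#'
#' @param meta a [survey_meta()].
#' @param households aggregate-mode household table, or NULL.
#' @param members individual-mode member listing, or NULL.
#' @param truth optional list of generator truth (synthetic surveys only).
#' @export
survey_dataset <- function(meta, households = NULL, members = NULL,
                           truth = NULL) {
  stopifnot(inherits(meta, "survey_meta"))
  if (meta$questionnaire == "individual" && is.null(members))
    stop("individual questionnaire requires a member listing")
  if (meta$questionnaire == "aggregate") {
    if (is.null(households)) stop("aggregate questionnaire requires household totals")
    if (!is.null(members)) stop("aggregate questionnaire carries no per-individual rows")
  }
  structure(list(meta = meta, households = households, members = members,
                 truth = truth), class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  n <- if (!is.null(x$households)) nrow(x$households)
       else length(unique(x$members$household))
  cat("<survey_dataset>", x$meta$survey_id, "in", x$meta$district,
      paste0("(", x$meta$questionnaire, ", ", x$meta$design, "),"),
      n, "households, recall", format(x$meta$recall_start), "to",
      format(x$meta$recall_end), "\n")
  invisible(x)
}

# Day weights of the calendar months a recall window intersects.
recall_month_weights <- function(recall_start, recall_end) {
  recall_start <- as.Date(recall_start); recall_end <- as.Date(recall_end)
  first <- ym(format(recall_start, "%Y-%m"))
  last <- ym(format(recall_end, "%Y-%m"))
  months <- seq.int(first, last)
  lo <- pmax(ym_date(months), recall_start)
  hi <- pmin(ym_date(months + 1L) - 1L, recall_end)
  data.frame(ym = months, days = as.numeric(hi - lo) + 1)
}

# Recall-window averaged continuous term values for one district, applying
# each term's lag by shifting the month weights back.
survey_term_values <- function(predictors, districts, district,
                               recall_start, recall_end,
                               schemes = default_term_schemes()) {
  w <- recall_month_weights(recall_start, recall_end)
  sub <- predictors[predictors$district == district, , drop = FALSE]
  out <- list(district = district)
  for (nm in names(schemes)) {
    defn <- schemes[[nm]]
    if (defn$type == "factor") next
    if (!nm %in% names(sub)) next
    k <- defn$scheme$lag
    v <- sub[[nm]][match(w$ym - k, sub$ym)]
    if (anyNA(v)) stop("recall window (lag ", k, ") not covered by panel for ",
                       district)
    out[[nm]] <- sum(v * w$days) / sum(w$days)
  }
  out$admin_level <- districts$admin_level[match(district, districts$district)]
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate SMART-style mortality surveys from a synthetic world
#'
#' Each survey samples one district and a 3-4 month recall window ending at
#' a month inside the world's range.  Household death counts are Poisson
#' with expectation `true rate x person-time`, where the survey-level true
#' rate applies the world's coefficients to recall-averaged, lag-shifted,
#' categorized predictor values — the same encoding the modelling stage
#' uses.  Under a cluster design, clusters carry a lognormal multiplicative
#' frailty on the rate (mean 1; variance `cluster_frailty_var`), inducing
#' intra-cluster correlation.  Under-5 deaths are generated first and
#' over-5 deaths added so that under-5 counts never exceed all-age counts
#' while both outcome expectations are exact.
#'
#' @param world a `synthetic_world`.
#' @param n_surveys number of surveys (>= 1).
#' @param design `"cluster"` or `"systematic"`.
#' @param questionnaire `"individual"` or `"aggregate"`.
#' @param recall_days_range inclusive range of recall lengths in days
#'   (within 60..150).
#' @param n_clusters,hh_per_cluster sample size per survey (cluster design);
#'   systematic surveys draw `n_clusters * hh_per_cluster` households.
#' @param cluster_frailty_var variance of the lognormal cluster frailty
#'   (default 0: no between-cluster heterogeneity).
#' @param mean_hh_size mean household size (shifted-Poisson; default 5.6).
#' @param seed integer seed.
#' @return list of [survey_dataset()] objects.
#' @export
generate_surveys <- function(world, n_surveys,
                             design = c("cluster", "systematic"),
                             questionnaire = c("individual", "aggregate"),
                             recall_days_range = c(80, 110),
                             n_clusters = 25L, hh_per_cluster = 20L,
                             cluster_frailty_var = 0,
                             mean_hh_size = 5.6,
                             seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"), n_surveys >= 1)
  design <- match.arg(design)
  questionnaire <- match.arg(questionnaire)
  if (recall_days_range[1] < 60 || recall_days_range[2] > 150)
    stop("recall range must lie within 60..150 days")
  cfg <- world$config
  with_seed(seed, {
    lapply(seq_len(n_surveys), function(s) {
      recall_days <- sample(seq.int(recall_days_range[1], recall_days_range[2]), 1L)
      # months whose recall window (and 6-month lags) the panel covers
      min_m <- world$months[1] + ceiling(recall_days / 28)
      m <- sample(world$months[world$months >= min_m], 1L)
      district <- sample(world$districts$district, 1L)
      recall_end <- ym_date(m + 1L) - 1L
      recall_start <- recall_end - recall_days + 1L
      tv <- survey_term_values(world$predictors, world$districts, district,
                               recall_start, recall_end, cfg$schemes)
      lp <- linpred_terms(encode_terms(tv, cfg$schemes), cfg$true_coefficients)
      cdr <- cfg$baseline_cdr * exp(lp)
      u5dr <- cfg$baseline_u5dr * exp(lp)

      n_hh <- n_clusters * hh_per_cluster
      cluster <- if (design == "cluster")
        rep(sprintf("c%02d", seq_len(n_clusters)), each = hh_per_cluster)
      else sprintf("h%04d", seq_len(n_hh))
      frailty <- if (design == "cluster" && cluster_frailty_var > 0) {
        sdl <- sqrt(log(1 + cluster_frailty_var))
        fc <- exp(stats::rnorm(n_clusters, -sdl^2 / 2, sdl))
        rep(fc, each = hh_per_cluster)
      } else rep(1, n_hh)

      size <- 1L + stats::rpois(n_hh, mean_hh_size - 1)
      u5 <- stats::rbinom(n_hh, size, cfg$under5_fraction)
      pd <- size * recall_days
      pd_u5 <- u5 * recall_days
      mu_u5 <- u5dr / 1e4 * pd_u5 * frailty
      deaths_u5 <- pmin(stats::rpois(n_hh, mu_u5), u5)
      mu_o5 <- pmax(0, cdr / 1e4 * pd - u5dr / 1e4 * pd_u5) * frailty
      deaths_o5 <- pmin(stats::rpois(n_hh, mu_o5), size - u5)
      deaths <- deaths_u5 + deaths_o5

      meta <- survey_meta(
        survey_id = sprintf("svy%03d", s), district = district,
        design = design, recall_start = recall_start,
        recall_end = recall_end, questionnaire = questionnaire)
      truth <- list(cdr = cdr, u5dr = u5dr, month = m,
                    term_values = tv)
      hh_id <- sprintf("hh%04d", seq_len(n_hh))
      if (questionnaire == "individual") {
        # member listing: everyone present for the full recall window; death
        # events flagged on listed members
        idx <- rep.int(seq_len(n_hh), size)
        n_mem <- length(idx)
        u5_flag <- sequence(size) <= u5[idx]
        died <- logical(n_mem)
        # flag deaths on members, under-5 deaths on under-5 members
        for (i in which(deaths > 0)) {
          mem <- which(idx == i)
          du5 <- mem[u5_flag[mem]][seq_len(deaths_u5[i])]
          do5 <- mem[!u5_flag[mem]][seq_len(deaths_o5[i])]
          died[c(du5, do5)] <- TRUE
        }
        members <- data.frame(
          household = hh_id[idx], cluster = cluster[idx],
          member = sprintf("m%06d", seq_len(n_mem)),
          under5 = u5_flag,
          entry = recall_start, exit = recall_end, died = died,
          stringsAsFactors = FALSE)
        survey_dataset(meta, members = members, truth = truth)
      } else {
        households <- data.frame(
          household = hh_id, cluster = cluster,
          n_end = size - deaths, u5_end = u5 - deaths_u5,
          births = 0L, joins = 0L, leaves = 0L,
          deaths = deaths, deaths_u5 = deaths_u5,
          stringsAsFactors = FALSE)
        survey_dataset(meta, households = households, truth = truth)
      }
    })
  })
}

#' Randomly delete reported under-5 deaths
#'
#' Emulates under-reporting of child deaths: each under-5 death is
#' independently removed with probability `p`; all-age deaths drop by the
#' same amount and person-time is left unchanged (a documented
#' simplification — the deleted deaths' person-time contribution is
#' negligible at survey scale).
#'
#' @param survey a [survey_dataset()].
#' @param p deletion probability in `[0, 1)`.
#' @param seed integer seed.
#' @return modified [survey_dataset()].
#' @export
apply_underreporting <- function(survey, p, seed = 1L) {
  stopifnot(inherits(survey, "survey_dataset"))
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  if (p == 0) return(survey)
  with_seed(seed, {
    if (survey$meta$questionnaire == "individual") {
      mm <- survey$members
      hit <- mm$died & mm$under5 & stats::runif(nrow(mm)) < p
      mm$died[hit] <- FALSE
      survey$members <- mm
    } else {
      hh <- survey$households
      removed <- stats::rbinom(nrow(hh), hh$deaths_u5, p)
      hh$deaths_u5 <- hh$deaths_u5 - removed
      hh$deaths <- hh$deaths - removed
      survey$households <- hh
    }
    survey
  })
}
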