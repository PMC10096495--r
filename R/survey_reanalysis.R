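#' Household person-time at risk
#'
#' Individual questionnaires list members with entry/exit dates: each member
#' contributes the days from `max(recall start, entry)` to
#' `min(recall end, exit)`, inclusive.  Aggregate questionnaires elicit only
#' end-of-recall member counts and event totals; person-days then follow the
#' mid-period convention
#' `recall_days * (N_end + 0.5 * (deaths + leaves - births - joins))`
#' (each event's unknown timing is placed at mid-recall).  For the under-5
#' stratum, births count as under-5 entries and joins/leaves are treated as
#' all-age only (their ages are not elicited).
#'
#' @param record one household: individual mode, a data.frame of member rows
#'   (`under5`, `entry`, `exit`); aggregate mode, a one-row data.frame or
#'   list with `n_end`, `u5_end`, `births`, `joins`, `leaves`, `deaths`,
#'   `deaths_u5`.
#' @param meta the survey's [survey_meta()].
#' @return named numeric: `pd` (all-age person-days) and `pd_u5`.
#' @export
compute_person_time <- function(record, meta) {
  recall_days <- as.numeric(meta$recall_end - meta$recall_start) + 1
  if (meta$questionnaire == "individual") {
    lo <- pmax(as.Date(record$entry), meta$recall_start)
    hi <- pmin(as.Date(record$exit), meta$recall_end)
    days <- pmax(0, as.numeric(hi - lo) + 1)
    c(pd = sum(days), pd_u5 = sum(days[record$under5]))
  } else {
    pd <- recall_days * (record$n_end +
      0.5 * (record$deaths + record$leaves - record$births - record$joins))
    pd_u5 <- recall_days * (record$u5_end +
      0.5 * (record$deaths_u5 - record$births))
    if (any(c(pd, pd_u5) < 0))
      stop("negative derived person-time: inconsistent member/event counts")
    c(pd = pd, pd_u5 = pd_u5)
  }
}

#' Canonical household person-time table of a survey
#'
#' Converts either questionnaire mode into one row per household with
#' cluster id, person-days (all-age and under-5) and death counts.
#' Households whose aggregate counts imply negative person-time are dropped;
#' the returned table carries them in `attr(, "rejected")` with the reason.
#'
#' @param survey a [survey_dataset()].
#' @return data.frame with columns `household`, `cluster`, `pd`, `pd_u5`,
#'   `deaths`, `deaths_u5`.
#' @export
survey_households <- function(survey) {
  meta <- survey$meta
  recall_days <- as.numeric(meta$recall_end - meta$recall_start) + 1
  if (meta$questionnaire == "individual") {
    mm <- survey$members
    lo <- pmax(as.Date(mm$entry), meta$recall_start)
    hi <- pmin(as.Date(mm$exit), meta$recall_end)
    days <- pmax(0, as.numeric(hi - lo) + 1)
    agg <- function(v) as.vector(rowsum(v, mm$household))
    ids <- sort(unique(mm$household))
    out <- data.frame(
      household = ids,
      cluster = mm$cluster[match(ids, mm$household)],
      pd = agg(days), pd_u5 = agg(days * mm$under5),
      deaths = agg(as.numeric(mm$died)),
      deaths_u5 = agg(as.numeric(mm$died & mm$under5)),
      stringsAsFactors = FALSE)
    attr(out, "rejected") <- out[0, ]
    out
  } else {
    hh <- survey$households
    pd <- recall_days * (hh$n_end +
      0.5 * (hh$deaths + hh$leaves - hh$births - hh$joins))
    pd_u5 <- recall_days * (hh$u5_end + 0.5 * (hh$deaths_u5 - hh$births))
    bad <- pd < 0 | pd_u5 < 0
    out <- data.frame(household = hh$household, cluster = hh$cluster,
                      pd = pd, pd_u5 = pmax(0, pd_u5),
                      deaths = hh$deaths, deaths_u5 = hh$deaths_u5,
                      stringsAsFactors = FALSE)
    rejected <- out[bad, , drop = FALSE]
    if (nrow(rejected)) rejected$reason <- "negative derived person-time"
    out <- out[!bad, , drop = FALSE]
    attr(out, "rejected") <- rejected
    out
  }
}

#' A death-rate estimate with cluster-robust uncertainty
#' @param rate deaths per 10,000 person-days.
#' @param ci_lower,ci_upper 95% confidence bounds.
#' @param se_log robust standard error of the log rate (NA when degenerate).
#' @param n_households,n_clusters,person_days,deaths totals behind the fit.
#' @export
rate_estimate <- function(rate, ci_lower, ci_upper, se_log,
                          n_households, n_clusters, person_days, deaths) {
  structure(list(rate = rate, ci_lower = ci_lower, ci_upper = ci_upper,
                 se_log = se_log, n_households = n_households,
                 n_clusters = n_clusters, person_days = person_days,
                 deaths = deaths), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.3f (95%% CI %.3f to %.3f) per 10,000 person-days [%d deaths / %.0f person-days, %d clusters]\n",
              x$rate, x$ci_lower, x$ci_upper, x$deaths, x$person_days,
              x$n_clusters))
  invisible(x)
}

#' Estimate CDR and U5DR from one survey
#'
#' Intercept-only household-level Poisson model with a log person-time
#' offset, so the point estimate equals `10,000 * sum(deaths) / sum(pd)`
#' exactly.  Standard errors are cluster-robust (CR0 sandwich, clustered on
#' the survey cluster; under a systematic design each household is its own
#' cluster), and the confidence interval is formed on the log scale with
#' normal quantiles, then exponentiated.  Zero-death surveys report rate 0
#' with a one-sided exact Poisson upper bound.
#'
#' @param survey a [survey_dataset()] (or a canonical household table with a
#'   `survey_meta` attached via `meta`).
#' @param conf_level confidence level (default 0.95).
#' @return list with elements `cdr` and `u5dr`, both [rate_estimate()]s.
#' @export
estimate_rates <- function(survey, conf_level = 0.95) {
  hh <- survey_households(survey)
  list(cdr = rate_from_households(hh$deaths, hh$pd, hh$cluster, conf_level),
       u5dr = rate_from_households(hh$deaths_u5, hh$pd_u5, hh$cluster,
                                   conf_level))
}

rate_from_households <- function(deaths, pd, cluster, conf_level = 0.95) {
  keep <- pd > 0
  deaths <- deaths[keep]; pd <- pd[keep]; cluster <- cluster[keep]
  if (!length(pd) || sum(pd) <= 0) stop("zero total person-time")
  n_cl <- length(unique(cluster))
  if (n_cl == 0L) stop("zero clusters")
  tot_d <- sum(deaths); tot_pd <- sum(pd)
  if (tot_d == 0) {
    # one-sided exact Poisson bound at the confidence level
    upper <- stats::qgamma(conf_level, shape = 1) / tot_pd * 1e4
    return(rate_estimate(0, 0, upper, NA_real_, length(pd), n_cl, tot_pd, 0))
  }
  df <- data.frame(deaths = deaths, pd = pd)
  fit <- stats::glm(deaths ~ 1 + offset(log(pd)),
                    family = stats::quasipoisson(), data = df)
  vc <- sandwich::vcovCL(fit, cluster = cluster, type = "HC0",
                         cadjust = FALSE)
  se <- sqrt(vc[1, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # the intercept-only MLE has the closed form log(sum d / sum pd); use it
  # directly so the GLM identity holds to machine precision
  lco <- log(tot_d / tot_pd)
  rate_estimate(exp(lco) * 1e4, exp(lco - z * se) * 1e4,
                exp(lco + z * se) * 1e4, unname(se),
                length(pd), n_cl, tot_pd, tot_d)
}

#' Simplified survey quality score
#'
#' A weighted checklist in `[0, 1]`: completeness of key metadata (0.4),
#' plausible mean household size 3-10 (0.2), plausible proportion under 5
#' in 0.10-0.45 (0.2), and a crude death-to-person-year ratio below 0.2
#' (0.2).  The score only feeds reporting, never weighting.
#'
#' @param survey a [survey_dataset()].
#' @return numeric in `[0, 1]`.
#' @export
quality_score <- function(survey) {
  meta <- survey$meta
  hh <- survey_households(survey)
  recall_days <- as.numeric(meta$recall_end - meta$recall_start) + 1
  score <- 0
  if (!is.na(meta$district) && !is.na(recall_days) &&
      meta$design %in% c("cluster", "systematic")) score <- score + 0.4
  mean_size <- mean(hh$pd) / recall_days
  if (is.finite(mean_size) && mean_size >= 3 && mean_size <= 10)
    score <- score + 0.2
  pu5 <- sum(hh$pd_u5) / sum(hh$pd)
  if (is.finite(pu5) && pu5 >= 0.10 && pu5 <= 0.45) score <- score + 0.2
  dr <- sum(hh$deaths) / (sum(hh$pd) / 365.25)
  if (is.finite(dr) && dr < 0.2) score <- score + 0.2
  score
}

#' Filter surveys for eligibility
#'
#' Retains surveys whose sampling universe is district-level (district,
#' urban or IDP-settlement within a district), whose sampling frame is
#' clear, and whose questionnaire and recall period are standard; surveys
#' ending before `min_year` (insufficient predictor coverage) are excluded
#' from modelling.  Surveys with missing metadata are excluded with reason
#' `"unclear"`.
#'
#' @param surveys list of [survey_dataset()]s or [survey_meta()]s.
#' @param min_year first calendar year usable for modelling (NULL = no
#'   restriction).
#' @return list with `eligible` (the retained surveys) and `exclusions`
#'   (data.frame of survey id and machine-readable reason).
#' @export
filter_eligible <- function(surveys, min_year = NULL) {
  metas <- lapply(surveys, function(s)
    if (inherits(s, "survey_dataset")) s$meta else s)
  reason <- vapply(metas, function(m) {
    if (is.null(m$universe) || is.na(m$universe) ||
        is.null(m$frame_clear) || is.na(m$frame_clear) ||
        is.na(m$recall_start) || is.na(m$recall_end)) return("unclear")
    if (m$universe == "livelihood_zone") return("livelihood_zone_universe")
    if (!isTRUE(m$frame_clear)) return("unclear_sampling_frame")
    if (!isTRUE(m$standard_questionnaire)) return("non_standard_questionnaire")
    if (!is.null(min_year) &&
        as.integer(format(m$recall_end, "%Y")) < min_year)
      return("outside_modelling_period")
    ""
  }, "")
  keep <- reason == ""
  exclusions <- data.frame(
    survey_id = vapply(metas, function(m) m$survey_id, ""),
    reason = reason, stringsAsFactors = FALSE)[!keep, , drop = FALSE]
  rownames(exclusions) <- NULL
  list(eligible = surveys[keep], exclusions = exclusions)
}

#' Per-survey estimates table
#'
#' One row per survey with CDR/U5DR point estimates and intervals plus
#' descriptive demographic indicators (mean household size, proportion
#' under 5, crude birth and net migration rates where the questionnaire
#' records events) and the simplified quality score.
#'
#' @param surveys list of [survey_dataset()]s.
#' @return data.frame, one row per survey.
#' @export
survey_estimates_table <- function(surveys) {
  rows <- lapply(surveys, function(s) {
    est <- estimate_rates(s)
    hh <- survey_households(s)
    recall_days <- as.numeric(s$meta$recall_end - s$meta$recall_start) + 1
    py <- sum(hh$pd) / 365.25
    ev <- if (s$meta$questionnaire == "aggregate") {
      b <- sum(s$households$births)
      net <- sum(s$households$joins) - sum(s$households$leaves)
      c(birth_rate = 1000 * b / py, net_migration_rate = 1000 * net / py)
    } else c(birth_rate = NA_real_, net_migration_rate = NA_real_)
    data.frame(
      survey_id = s$meta$survey_id, district = s$meta$district,
      recall_start = s$meta$recall_start, recall_end = s$meta$recall_end,
      questionnaire = s$meta$questionnaire, design = s$meta$design,
      n_households = nrow(hh), n_clusters = length(unique(hh$cluster)),
      cdr = est$cdr$rate, cdr_lci = est$cdr$ci_lower, cdr_uci = est$cdr$ci_upper,
      u5dr = est$u5dr$rate, u5dr_lci = est$u5dr$ci_lower,
      u5dr_uci = est$u5dr$ci_upper,
      mean_hh_size = mean(hh$pd) / recall_days,
      prop_under5 = sum(hh$pd_u5) / sum(hh$pd),
      birth_rate = ev[["birth_rate"]],
      net_migration_rate = ev[["net_migration_rate"]],
      quality_score = quality_score(s),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
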