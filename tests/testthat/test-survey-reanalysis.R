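meta_ind <- survey_meta("s1", "d01", recall_start = as.Date("2017-01-01"),
                        recall_end = as.Date("2017-04-10"),
                        questionnaire = "individual")

test_that("individual person-time counts member-days inside the recall window", {
  # 5 members present for the full 100-day recall
  rec <- data.frame(under5 = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                    entry = as.Date("2016-12-01"), exit = as.Date("2017-05-01"))
  pt <- compute_person_time(rec, meta_ind)
  expect_equal(pt[["pd"]], 500)
  expect_equal(pt[["pd_u5"]], 200)

  # member born at the midpoint of a 120-day recall contributes 60 days
  meta120 <- survey_meta("s2", "d01", recall_start = as.Date("2017-01-01"),
                         recall_end = as.Date("2017-04-30"),
                         questionnaire = "individual")
  born <- data.frame(under5 = TRUE, entry = as.Date("2017-01-01") + 60,
                     exit = as.Date("2017-12-31"))
  expect_equal(compute_person_time(born, meta120)[["pd"]], 60)
})

test_that("aggregate person-time follows the mid-period convention", {
  meta <- survey_meta("s3", "d01", recall_start = as.Date("2017-01-01"),
                      recall_end = as.Date("2017-04-10"),
                      questionnaire = "aggregate")
  rec <- list(n_end = 6, u5_end = 2, births = 0, joins = 0, leaves = 0,
              deaths = 1, deaths_u5 = 0)
  expect_equal(compute_person_time(rec, meta)[["pd"]], 100 * 6.5)
  # inconsistent counts imply negative person-time and are rejected
  bad <- list(n_end = 0, u5_end = 0, births = 10, joins = 0, leaves = 0,
              deaths = 0, deaths_u5 = 0)
  expect_error(compute_person_time(bad, meta), "negative derived person-time")
})

test_that("intercept-only rate equals total deaths over person-time exactly", {
  s <- handmade_survey(deaths = c(1, 1, 0, 0), pd = rep(10000, 4))
  est <- estimate_rates(s)$cdr
  expect_equal(est$rate, 1e4 * 2 / 40000, tolerance = 1e-10)
  expect_equal(est$rate, 0.5, tolerance = 1e-10)
  expect_lte(est$ci_lower, est$rate)
  expect_gte(est$ci_upper, est$rate)

  # also exact on a simulated survey
  sv <- tiny_surveys()[[1]]
  hh <- survey_households(sv)
  expect_equal(estimate_rates(sv)$cdr$rate, 1e4 * sum(hh$deaths) / sum(hh$pd),
               tolerance = 1e-10)
})

test_that("zero-death surveys report rate 0 with an exact upper bound", {
  s <- handmade_survey(deaths = c(0, 0, 0, 0))
  est <- estimate_rates(s)$cdr
  expect_equal(est$rate, 0)
  expect_equal(est$ci_lower, 0)
  expect_equal(est$ci_upper, stats::qgamma(0.95, 1) / 40000 * 1e4)
})

test_that("rate estimation is invariant to household row order", {
  sv <- tiny_surveys()[[2]]
  est1 <- estimate_rates(sv)
  sv2 <- sv
  perm <- rev(seq_len(nrow(sv2$members)))
  sv2$members <- sv2$members[perm, ]
  est2 <- estimate_rates(sv2)
  expect_equal(est1$cdr$rate, est2$cdr$rate)
  expect_equal(est1$cdr$se_log, est2$cdr$se_log)
})

test_that("with one household per cluster the robust SE matches HC0", {
  s <- handmade_survey(deaths = c(2, 1, 0, 1), pd = c(9000, 11000, 8000, 12000),
                       clusters = paste0("c", 1:4))
  est <- estimate_rates(s)$cdr
  hh <- survey_households(s)
  fit <- stats::glm(deaths ~ 1 + offset(log(pd)),
                    family = stats::quasipoisson(), data = hh)
  se_hc0 <- sqrt(sandwich::vcovHC(fit, type = "HC0")[1, 1])
  expect_equal(est$se_log, se_hc0, tolerance = 1e-10)
})

test_that("confidence intervals cover the true rate at close to nominal level", {
  zero <- lapply(default_true_coefficients(), function(v) v * 0)
  w <- generate_world(world_config(n_districts = 4, n_regions = 2,
                                   true_coefficients = zero,
                                   baseline_cdr = 0.43, seed = 61))
  hits <- vapply(1:300, function(r) {
    s <- generate_surveys(w, 1, n_clusters = 20L, hh_per_cluster = 18L,
                          seed = 6000 + r)[[1]]
    est <- estimate_rates(s)$cdr
    est$ci_lower <= 0.43 && 0.43 <= est$ci_upper
  }, TRUE)
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("eligibility filtering counts exclusions by machine-readable reason", {
  mk <- function(i, universe = "district", frame = TRUE, std = TRUE,
                 year = 2016) {
    survey_meta(sprintf("m%03d", i), "d01", universe = universe,
                frame_clear = frame, standard_questionnaire = std,
                recall_start = as.Date(sprintf("%d-01-01", year)),
                recall_end = as.Date(sprintf("%d-04-01", year)))
  }
  metas <- c(lapply(1:87, mk, universe = "livelihood_zone"),
             lapply(88:98, mk, frame = FALSE),
             lapply(99:104, mk, std = FALSE),
             lapply(105:110, mk, year = 2013),
             lapply(111:201, mk))
  res <- filter_eligible(metas, min_year = 2014)
  expect_length(res$eligible, 91)
  tab <- table(res$exclusions$reason)
  expect_equal(tab[["livelihood_zone_universe"]], 87)
  expect_equal(tab[["unclear_sampling_frame"]], 11)
  expect_equal(tab[["non_standard_questionnaire"]], 6)
  expect_equal(tab[["outside_modelling_period"]], 6)

  empty <- filter_eligible(list())
  expect_length(empty$eligible, 0)
  expect_equal(nrow(empty$exclusions), 0)

  keepall <- filter_eligible(metas[111:120])
  expect_length(keepall$eligible, 10)
})

test_that("the estimates table mirrors the survey descriptive columns", {
  sv <- tiny_surveys()[1:3]
  tab <- survey_estimates_table(sv)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("cdr", "cdr_lci", "cdr_uci", "u5dr", "mean_hh_size",
                    "prop_under5", "quality_score") %in% names(tab)))
  expect_true(all(tab$mean_hh_size > 3 & tab$mean_hh_size < 9))
  expect_true(all(tab$prop_under5 > 0.1 & tab$prop_under5 < 0.4))
  expect_true(all(tab$quality_score >= 0 & tab$quality_score <= 1))
})
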