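test_that("world generation is deterministic field for field", {
  w1 <- generate_world(world_config(n_districts = 5, n_regions = 2, seed = 3))
  w2 <- generate_world(world_config(n_districts = 5, n_regions = 2, seed = 3))
  expect_identical(w1$districts, w2$districts)
  expect_identical(w1$predictors, w2$predictors)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$flows, w2$flows)
  expect_identical(lapply(w1$anchors, unclass), lapply(w2$anchors, unclass))
  w3 <- generate_world(world_config(n_districts = 5, n_regions = 2, seed = 4))
  expect_false(identical(w1$truth, w3$truth))
})

test_that("config validation rejects malformed worlds", {
  expect_error(world_config(n_districts = 1), "at least 2")
  expect_error(world_config(month_range = c("2014-01", "2014-12")),
               "at least 24 months")
  expect_error(world_config(baseline_cdr = 0), "positive")
  expect_error(world_config(under5_fraction = 1), "\\(0, 1\\)")
  expect_error(world_config(true_coefficients = list(cholera = c(x = 1))),
               "unknown predictor term")
  expect_error(
    world_config(true_coefficients = list(conflict = c("no-such-level" = 1))),
    "unknown level")
})

test_that("null coefficients give a flat true rate at the baseline", {
  zero <- lapply(default_true_coefficients(), function(v) v * 0)
  w <- generate_world(world_config(n_districts = 4, n_regions = 2,
                                   true_coefficients = zero,
                                   baseline_cdr = 0.5, seed = 8))
  expect_equal(unique(w$truth$log_cdr), log(0.5))
  # constant in time for every district
  for (d in unique(w$truth$district))
    expect_equal(stats::sd(w$truth$log_cdr[w$truth$district == d]), 0)
})

test_that("a single conflict coefficient reproduces its rate ratio exactly", {
  cf <- list(conflict = c("0.25-0.49" = 0, ">=0.50" = log(1.60)))
  w <- generate_world(world_config(n_districts = 4, n_regions = 2,
                                   true_coefficients = cf, seed = 9))
  sch <- default_term_schemes()$conflict$scheme
  lev <- as.character(categorize(w$predictors$conflict, sch))
  key <- paste(w$predictors$district, w$predictors$ym)
  lev <- lev[match(paste(w$truth$district, w$truth$ym), key)]
  ratio <- exp(w$truth$log_cdr) / w$config$baseline_cdr
  expect_equal(unique(ratio[lev == ">=0.50"]), 1.60)
  expect_equal(unique(ratio[lev != ">=0.50"]), 1.00)
})

test_that("true rates are positive, flows non-negative and bounded by stock", {
  w <- tiny_world()
  expect_true(all(is.finite(w$truth$log_cdr)))
  expect_true(all(w$truth$pop > 0))
  expect_true(all(w$flows$persons >= 0))
  out <- tapply(w$flows$persons[!is.na(w$flows$origin)],
                list(w$flows$origin[!is.na(w$flows$origin)],
                     w$flows$ym[!is.na(w$flows$origin)]), sum)
  for (d in rownames(out)) for (m in colnames(out)) {
    if (is.na(out[d, m])) next
    pop <- w$truth$pop[w$truth$district == d & w$truth$ym == as.integer(m)]
    expect_lt(out[d, m], pop)
  }
})

test_that("pooled survey death rate converges to the configured truth", {
  zero <- lapply(default_true_coefficients(), function(v) v * 0)
  w <- generate_world(world_config(n_districts = 4, n_regions = 2,
                                   true_coefficients = zero,
                                   baseline_cdr = 0.5, baseline_u5dr = 0.75,
                                   seed = 21))
  # ~4,000 households x ~5.6 members x ~100 days > 10^6 person-days
  sv <- generate_surveys(w, 4, n_clusters = 40L, hh_per_cluster = 25L,
                         seed = 22)
  hh <- do.call(rbind, lapply(sv, survey_households))
  expect_gt(sum(hh$pd), 1e6)
  est <- 1e4 * sum(hh$deaths) / sum(hh$pd)
  mc_se <- 1e4 * sqrt(sum(hh$deaths)) / sum(hh$pd)
  expect_lt(abs(est - 0.5), 3 * mc_se)
})

test_that("zero cluster frailty yields a design effect near one", {
  w <- tiny_world()
  deff <- vapply(1:12, function(r) {
    s <- generate_surveys(w, 1, cluster_frailty_var = 0,
                          seed = 4000 + r)[[1]]
    hh <- survey_households(s)
    if (sum(hh$deaths) < 2) return(NA_real_)
    est <- estimate_rates(s)$cdr
    (est$se_log / (1 / sqrt(est$deaths)))^2
  }, 0)
  expect_equal(mean(deff, na.rm = TRUE), 1, tolerance = 0.25)
})

test_that("frailty induces a design effect above one", {
  w <- tiny_world()
  deff <- vapply(1:12, function(r) {
    s <- generate_surveys(w, 1, cluster_frailty_var = 0.5,
                          n_clusters = 30L, hh_per_cluster = 25L,
                          seed = 4100 + r)[[1]]
    est <- estimate_rates(s)$cdr
    if (est$deaths < 5) return(NA_real_)
    (est$se_log / (1 / sqrt(est$deaths)))^2
  }, 0)
  expect_gt(mean(deff, na.rm = TRUE), 1.3)
})

test_that("aggregate questionnaires carry no per-individual rows", {
  w <- tiny_world()
  s <- generate_surveys(w, 1, questionnaire = "aggregate", seed = 5)[[1]]
  expect_null(s$members)
  expect_s3_class(s, "survey_dataset")
  expect_error(survey_dataset(s$meta, households = s$households,
                              members = data.frame(x = 1)),
               "no per-individual rows")
})

test_that("survey generation validates the recall range and is seed-stable", {
  w <- tiny_world()
  expect_error(generate_surveys(w, 1, recall_days_range = c(30, 90)),
               "60..150")
  s1 <- generate_surveys(w, 2, seed = 77)
  s2 <- generate_surveys(w, 2, seed = 77)
  expect_identical(lapply(s1, function(s) s$members),
                   lapply(s2, function(s) s$members))
  expect_identical(s1[[1]]$meta$recall_start, s2[[1]]$meta$recall_start)
})

test_that("under-reporting deletes the expected share of under-5 deaths", {
  w <- tiny_world()
  s <- generate_surveys(w, 1, n_clusters = 40L, hh_per_cluster = 25L,
                        seed = 31)[[1]]
  base_u5 <- sum(survey_households(s)$deaths_u5)
  expect_gt(base_u5, 10)

  expect_identical(apply_underreporting(s, 0, seed = 1), s)

  hi <- apply_underreporting(s, 0.999, seed = 2)
  expect_lte(sum(survey_households(hi)$deaths_u5), 1)

  kept <- vapply(1:40, function(r)
    sum(survey_households(apply_underreporting(s, 0.5, seed = r))$deaths_u5), 0)
  # binomial mean check at 3 Monte-Carlo SEs
  mc_se <- sqrt(base_u5 * 0.25 / 40)
  expect_lt(abs(mean(kept) - base_u5 / 2), 3 * mc_se)
  # all-age deaths reduced by the same amount
  one <- apply_underreporting(s, 0.5, seed = 9)
  hh0 <- survey_households(s); hh1 <- survey_households(one)
  expect_equal(sum(hh0$deaths) - sum(hh1$deaths),
               sum(hh0$deaths_u5) - sum(hh1$deaths_u5))
  expect_error(apply_underreporting(s, 1), "\\[0, 1\\)")
})
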