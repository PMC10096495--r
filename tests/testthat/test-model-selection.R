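two_group_data <- function(d0 = 8, t0 = 80000, d1 = 12, t1 = 40000) {
  # two "surveys", one per exposure group, many 1-household clusters
  mk <- function(g, d, t, n = 40) {
    deaths <- rep(0L, n); deaths[seq_len(d)] <- 1L
    data.frame(survey_id = paste0("s", g), cluster_id = paste0(g, seq_len(n)),
               deaths = deaths, pd = t / n, deaths_u5 = 0, pd_u5 = t / (2 * n),
               grp = factor(g, levels = c("g0", "g1")),
               stringsAsFactors = FALSE)
  }
  rbind(mk("g0", d0, t0), mk("g1", d1, t1))
}

test_that("intercept-only fit recovers the pooled rate in closed form", {
  dat <- two_group_data(d0 = 2, t0 = 40000, d1 = 0, t1 = 1)
  dat <- dat[dat$survey_id == "sg0", ]
  fit <- fit_quasipoisson(dat, model_spec("CDR"))
  expect_equal(unname(exp(fit$coefficients[1])), 5e-5, tolerance = 1e-8)
})

test_that("a binary covariate recovers the two-group log rate ratio exactly", {
  dat <- two_group_data()
  fit <- fit_quasipoisson(dat, model_spec("CDR", "grp"))
  expect_equal(unname(fit$coefficients["grpg1"]),
               log((12 / 40000) / (8 / 80000)), tolerance = 1e-6)
})

test_that("quasi-Poisson point estimates equal the Poisson MLE", {
  md <- tiny_model_data()
  spec <- model_spec("CDR", c("conflict", "malaria"))
  fit <- fit_quasipoisson(md, spec)
  pois <- stats::glm(deaths ~ conflict + malaria + offset(log(pd)),
                     family = stats::poisson(), data = md)
  expect_equal(fit$coefficients, stats::coef(pois), tolerance = 1e-8)
  expect_gt(fit$dispersion, 0)
  # robust covariance is symmetric PSD
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
})

test_that("rank deficiency is reported, not silently dropped", {
  md <- tiny_model_data()
  md$dup <- md$conflict
  expect_error(fit_quasipoisson(md, model_spec("CDR", c("conflict", "dup"))),
               "rank-deficient")
})

test_that("the Dawid-Sebastiani score matches hand computation", {
  expect_equal(dss(1, 1, 1), 0, tolerance = 1e-12)
  expect_equal(dss(3, 1, 1), 4, tolerance = 1e-12)
  expect_equal(dss(0, 2, 2 * 2), 1 + log(4), tolerance = 1e-12)
  expect_equal(dss(c(1, 3), c(1, 1), c(1, 1)), c(0, 4), tolerance = 1e-12)
  expect_error(dss(1, 1, 0), "positive")
})

test_that("cross-validation partitions surveys and is seed-stable", {
  md <- tiny_model_data()
  spec <- model_spec("CDR", "conflict")
  s1 <- cross_validate(md, spec, k = 5, seed = 3)
  s2 <- cross_validate(md, spec, k = 5, seed = 3)
  expect_identical(s1, s2)
  s3 <- cross_validate(md, spec, k = 5, seed = 4)
  expect_false(identical(as.numeric(s1), as.numeric(s3)))
  # leave-one-survey-out at k = number of surveys
  k <- length(unique(md$survey_id))
  loo <- cross_validate(md, spec, k = k, seed = 1)
  expect_length(attr(loo, "folds"), k)
  expect_error(cross_validate(md, spec, k = k + 1, seed = 1), "at least k")
})

test_that("duplicated surveys in complementary folds score identically", {
  dat <- two_group_data()
  dat2 <- dat
  dat2$survey_id <- paste0(dat2$survey_id, "_copy")
  dat2$cluster_id <- paste0(dat2$cluster_id, "_copy")
  both <- rbind(dat, dat2)
  folds <- c(sg0 = 1L, sg1 = 1L, sg0_copy = 2L, sg1_copy = 2L)
  cv <- cross_validate(both, model_spec("CDR", "grp"), folds = folds)
  f <- attr(cv, "folds")
  expect_equal(f[[1]], f[[2]], tolerance = 1e-10)
})

test_that("the intercept-only CV score ignores predictor panel contents", {
  md <- tiny_model_data()
  md2 <- md
  md2$conflict_value <- md2$conflict_value * 10
  md2$sam <- factor(">=200", levels = levels(md$sam))
  folds <- crisismort:::make_folds(md$survey_id, 5, 1)
  expect_identical(cross_validate(md, model_spec("CDR"), folds = folds),
                   cross_validate(md2, model_spec("CDR"), folds = folds))
})

test_that("screening keeps informative predictors and drops pure noise", {
  # survey-level noise factor vs the true generative conflict predictor;
  # decisions evaluated at the default margin (0) and a small margin that
  # trades a little sensitivity for far fewer false inclusions
  impr <- t(vapply(1:12, function(r) {
    w <- generate_world(world_config(n_districts = 10, n_regions = 4,
                                     seed = 800 + r))
    sv <- generate_surveys(w, 40, seed = 900 + r)
    md <- survey_model_data(sv, w$predictors, w$districts)
    set.seed(1000 + r)
    ids <- unique(md$survey_id)
    lv <- sample(c("lo", "hi"), length(ids), replace = TRUE)
    md$noise <- factor(lv[match(md$survey_id, ids)], levels = c("lo", "hi"))
    keep <- screen_predictors(c("conflict", "noise"), md, k = 10,
                              seed = 1100 + r)
    sc <- attr(keep, "scores")
    c(conflict = sc[["(intercept)"]] - sc[["conflict"]],
      noise = sc[["(intercept)"]] - sc[["noise"]])
  }, c(0, 0)))
  expect_gte(mean(impr[, "conflict"] > 0), 0.9)      # margin 0
  expect_gte(mean(impr[, "noise"] <= 0), 0.6)
  expect_gte(mean(impr[, "conflict"] > 0.01), 0.9)   # margin 0.01
  expect_gte(mean(impr[, "noise"] <= 0.01), 0.9)
  # the true predictor separates clearly from noise on average
  expect_gt(mean(impr[, "conflict"]), mean(impr[, "noise"]) + 0.02)
})

test_that("brute-force search enumerates, ranks and shortlists as stated", {
  md <- tiny_model_data()
  lb <- brute_force_search(c("conflict", "malaria", "measles"), md,
                           k = 5, seed = 2)
  expect_equal(nrow(lb), 8)                       # 2^3 subsets
  expect_equal(sum(lb$n_terms == 0), 1)
  expect_false(is.unsorted(lb$cv_dss))
  # independent re-scoring pass reproduces the ranking
  lb2 <- brute_force_search(c("conflict", "malaria", "measles"), md,
                            k = 5, seed = 2)
  expect_identical(lb$spec_id, lb2$spec_id)
  expect_equal(lb$cv_dss, lb2$cv_dss)
  # top-20% of 8 models is ceiling(1.6) = 2
  sh <- shortlist(lb, 0.2)
  expect_equal(nrow(sh), 2)
  expect_length(attr(sh, "specs"), 2)
  # enumeration guard
  expect_error(brute_force_search(letters[1:12], md, cap = 1024), "cap")
  # max_terms restricts the subset sizes searched
  lb1 <- brute_force_search(c("conflict", "malaria", "measles"), md,
                            max_terms = 1, k = 5, seed = 2)
  expect_equal(nrow(lb1), 4)
})

test_that("holdout validation validates its inputs and is seed-stable", {
  md <- tiny_model_data()
  expect_error(holdout_validate(md, model_spec("CDR"), train_frac = 1),
               "strictly between")
  h1 <- holdout_validate(md, model_spec("CDR", "conflict"), seed = 5)
  h2 <- holdout_validate(md, model_spec("CDR", "conflict"), seed = 5)
  expect_identical(h1, h2)
})

test_that("the true model outperforms intercept-only on holdout data", {
  wins <- vapply(1:10, function(r) {
    w <- generate_world(world_config(n_districts = 10, n_regions = 4,
                                     seed = 1200 + r))
    sv <- generate_surveys(w, 30, seed = 1300 + r)
    md <- survey_model_data(sv, w$predictors, w$districts)
    h_true <- holdout_validate(md, model_spec("CDR", all_terms()),
                               seed = 1400 + r)
    h_null <- holdout_validate(md, model_spec("CDR"), seed = 1400 + r)
    h_true <= h_null
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("model selection applies the documented deterministic rule", {
  md <- tiny_model_data()
  lb <- brute_force_search(c("conflict", "malaria"), md, k = 5, seed = 2)
  sh <- shortlist(lb, 0.5)
  pick <- select_model(sh, md, seed = 6)
  tab <- attr(pick, "table")
  expect_s3_class(pick, "model_spec")
  expect_equal(attr(pick, "rule"), "lowest holdout DSS, then fewest parameters")
  expect_equal(spec_min <- tab$spec_id[which.min(tab$holdout_dss)],
               spec_id <- crisismort:::spec_id(pick))
})
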