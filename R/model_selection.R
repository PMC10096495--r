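#' Specification of a candidate mortality model
#'
#' @param outcome `"CDR"` (all-age) or `"U5DR"` (under-5): chooses the death
#'   count and the person-time offset.
#' @param terms character vector of predictor term names (unique; at most
#'   `max_terms`).  Empty = intercept-only.
#' @param max_terms maximum number of terms (default 6).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("CDR", "U5DR"), terms = character(),
                       max_terms = 6L) {
  outcome <- match.arg(outcome)
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("model terms must be unique")
  if (length(terms) > max_terms)
    stop("more than ", max_terms, " terms in model spec")
  structure(list(outcome = outcome, terms = terms,
                 max_terms = as.integer(max_terms)), class = "model_spec")
}

spec_id <- function(spec) {
  if (!length(spec$terms)) "(intercept)" else paste(spec$terms, collapse = "+")
}

# Household modelling rows for the spec's outcome: y, pt, cluster_id and the
# encoded term columns.
outcome_frame <- function(data, spec) {
  if (spec$outcome == "CDR") {
    df <- data; df$y <- data$deaths; df$pt <- data$pd
  } else {
    df <- data[data$pd_u5 > 0, , drop = FALSE]
    df$y <- df$deaths_u5; df$pt <- df$pd_u5
  }
  df
}

#' Fit a household-level quasi-Poisson mortality model
#'
#' Death counts are modelled with a log link and a log person-time offset,
#' so coefficients are log rate ratios.  The dispersion is the Pearson
#' chi-square over residual degrees of freedom; the coefficient covariance
#' is the CR0 sandwich clustered on the survey cluster id.  Point estimates
#' are identical to the Poisson MLE (the dispersion only scales the
#' model-based covariance).
#'
#' @param data household modelling rows: `deaths`, `pd`, `deaths_u5`,
#'   `pd_u5`, `cluster_id`, and one encoded factor column per candidate
#'   term (see [survey_model_data()]).
#' @param spec a [model_spec()].
#' @return object of class `fitted_mortality_model` with elements
#'   `coefficients`, `dispersion`, `vcov` (robust), `spec`, `glm` (stripped
#'   fit used for prediction) and `n` (training-data summary).
#' @export
fit_quasipoisson <- function(data, spec) {
  df <- outcome_frame(data, spec)
  if (any(df$pt <= 0)) stop("non-positive person-time in modelling rows")
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste("y ~", rhs, "+ offset(log(pt))"))
  fit <- stats::glm(form, family = stats::quasipoisson(), data = df)
  if (!fit$converged) stop("quasi-Poisson fit did not converge for spec ",
                           spec_id(spec))
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design matrix for spec ", spec_id(spec))
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  vc <- sandwich::vcovCL(fit, cluster = df$cluster_id, type = "HC0",
                         cadjust = FALSE)
  # strip pieces predict() does not need; keeps bootstrap loops light
  slim <- fit
  slim$model <- NULL; slim$data <- NULL; slim$y <- NULL
  slim$residuals <- NULL; slim$weights <- NULL; slim$prior.weights <- NULL
  slim$fitted.values <- NULL; slim$effects <- NULL
  slim$linear.predictors <- NULL; slim$qr$qr <- NULL
  structure(list(coefficients = stats::coef(fit), dispersion = phi,
                 vcov = vc, spec = spec, glm = slim,
                 n = c(households = nrow(df),
                       clusters = length(unique(df$cluster_id)),
                       deaths = sum(df$y), person_days = sum(df$pt))),
            class = "fitted_mortality_model")
}

#' @export
print.fitted_mortality_model <- function(x, ...) {
  cat("<fitted_mortality_model>", x$spec$outcome, "~", spec_id(x$spec),
      sprintf("\n  dispersion %.3f; %d households, %d clusters, %d deaths\n",
              x$dispersion, x$n[["households"]], x$n[["clusters"]],
              x$n[["deaths"]]))
  invisible(x)
}

#' Rate-ratio table of a fitted model
#'
#' @param model a `fitted_mortality_model`.
#' @param conf_level confidence level (default 0.95, robust normal-quantile
#'   intervals on the log scale).
#' @return data.frame: term coefficient, log rate ratio, robust SE, rate
#'   ratio and interval.
#' @export
coef_table <- function(model, conf_level = 0.95) {
  b <- model$coefficients
  se <- sqrt(diag(model$vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(coefficient = names(b), log_rr = as.numeric(b),
             robust_se = as.numeric(se), rr = exp(as.numeric(b)),
             rr_lci = exp(as.numeric(b) - z * se),
             rr_uci = exp(as.numeric(b) + z * se),
             stringsAsFactors = FALSE)
}

#' Dawid-Sebastiani score
#'
#' `(y - mu)^2 / sigma2 + log(sigma2)`; a proper scoring rule for
#' predictive distributions summarised by mean and variance (lower is
#' better).  For quasi-Poisson predictions the variance is
#' `dispersion * mu`.  Means are floored at `mu_floor` so degenerate
#' predictions keep the log finite.
#'
#' @param y observed count.
#' @param mu predicted mean.
#' @param sigma2 predictive variance (> 0).
#' @export
dss <- function(y, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("predictive variance must be positive")
  (y - mu)^2 / sigma2 + log(sigma2)
}

# Design matrix for new rows, aligned to the fitted coefficients.  Factor
# levels never observed in training (whose columns glm dropped) fall back to
# the reference level's prediction.
design_for <- function(model, data) {
  tt <- stats::delete.response(stats::terms(model$glm))
  X <- stats::model.matrix(tt, data = data)
  miss <- setdiff(names(model$coefficients), colnames(X))
  if (length(miss))
    stop("prediction frame lacks design columns: ", paste(miss, collapse = ", "))
  X[, names(model$coefficients), drop = FALSE]
}

# Predicted mean count for modelling rows (includes the person-time offset).
model_mu <- function(model, df) {
  as.numeric(exp(design_for(model, df) %*% model$coefficients + log(df$pt)))
}

# Mean household DSS of `model` on `newdata` rows, using the training
# dispersion as the predictive variance factor.
dss_score <- function(model, newdata, mu_floor = 1e-12) {
  df <- outcome_frame(newdata, model$spec)
  mu <- pmax(model_mu(model, df), mu_floor)
  mean(dss(df$y, mu, model$dispersion * mu))
}

make_folds <- function(ids, k, seed) {
  ids <- unique(ids)
  if (length(ids) < k) stop("need at least k surveys for k folds")
  with_seed(seed, stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids))
}

#' Survey-level k-fold cross-validated mean DSS
#'
#' Folds partition surveys (not households), respecting the sampling
#' structure; each fold's held-out households are scored with the training
#' fit's dispersion, and the unweighted mean over folds is returned.
#'
#' @param data household modelling rows with a `survey_id` column.
#' @param spec a [model_spec()].
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param folds optional precomputed survey -> fold assignment (named
#'   integer), e.g. to score many specs on identical folds.
#' @return mean cross-validated DSS (lower is better); per-fold scores in
#'   `attr(, "folds")`.
#' @export
cross_validate <- function(data, spec, k = 10L, seed = 1L, folds = NULL) {
  if (is.null(folds)) folds <- make_folds(data$survey_id, k, seed)
  fold_of <- folds[data$survey_id]
  scores <- vapply(sort(unique(folds)), function(f) {
    train <- data[fold_of != f, , drop = FALSE]
    test <- data[fold_of == f, , drop = FALSE]
    fit <- fit_quasipoisson(train, spec)
    dss_score(fit, test)
  }, 0)
  structure(mean(scores), folds = scores)
}

#' Screen candidate predictors by single-term fit
#'
#' Keeps candidates whose single-predictor model improves the mean
#' cross-validated DSS over the intercept-only model by more than `margin`
#' (default 0).
#'
#' @param candidates character vector of term names.
#' @param data household modelling rows.
#' @param outcome `"CDR"` or `"U5DR"`.
#' @param k,seed cross-validation settings.
#' @param margin required DSS improvement (default 0).
#' @return retained candidate names; per-candidate DSS in
#'   `attr(, "scores")`.
#' @export
screen_predictors <- function(candidates, data, outcome = "CDR", k = 10L,
                              seed = 1L, margin = 0) {
  if (!length(candidates)) return(character())
  folds <- make_folds(data$survey_id, k, seed)
  null_dss <- as.numeric(cross_validate(data, model_spec(outcome), folds = folds))
  scores <- vapply(candidates, function(p)
    as.numeric(cross_validate(data, model_spec(outcome, p), folds = folds)), 0)
  keep <- candidates[null_dss - scores > margin]
  attr(keep, "scores") <- c("(intercept)" = null_dss, scores)
  keep
}

#' Brute-force search over candidate models
#'
#' Fits and cross-validates every subset of the candidate terms (up to
#' `max_terms` terms), on identical folds, and ranks ascending by mean DSS;
#' ties break by fewer parameters, then lexicographic spec.  Refuses
#' outright when the subset count exceeds `cap`.
#'
#' @param candidates character vector of screened term names.
#' @param data household modelling rows.
#' @param outcome `"CDR"` or `"U5DR"`.
#' @param max_terms largest model size searched (default 6).
#' @param k,seed cross-validation settings.
#' @param cap maximum number of subsets enumerated (default 1024).
#' @return data.frame leaderboard: `spec_id`, `n_terms`, `cv_dss`, ranked;
#'   specs as list in `attr(, "specs")`.
#' @export
brute_force_search <- function(candidates, data, outcome = "CDR",
                               max_terms = 6L, k = 10L, seed = 1L,
                               cap = 1024L) {
  n_sub <- 2^length(candidates)
  if (n_sub > cap)
    stop("candidate set implies ", n_sub, " subsets, above the cap of ", cap)
  subsets <- lapply(seq_len(n_sub) - 1L, function(m)
    candidates[bitwAnd(m, 2^(seq_along(candidates) - 1L)) > 0])
  subsets <- subsets[lengths(subsets) <= max_terms]
  folds <- make_folds(data$survey_id, k, seed)
  specs <- lapply(subsets, function(s) model_spec(outcome, s, max_terms))
  scores <- vapply(specs, function(sp)
    as.numeric(cross_validate(data, sp, folds = folds)), 0)
  lb <- data.frame(spec_id = vapply(specs, spec_id, ""),
                   n_terms = lengths(subsets), cv_dss = scores,
                   stringsAsFactors = FALSE)
  ord <- order(lb$cv_dss, lb$n_terms, lb$spec_id)
  lb <- lb[ord, ]; rownames(lb) <- NULL
  attr(lb, "specs") <- specs[ord]
  lb
}

#' Top share of a ranked leaderboard
#' @param leaderboard output of [brute_force_search()].
#' @param frac shortlist fraction (default 0.2); `ceiling(frac * n)` models
#'   are kept.
#' @export
shortlist <- function(leaderboard, frac = 0.2) {
  n <- ceiling(frac * nrow(leaderboard))
  out <- leaderboard[seq_len(n), , drop = FALSE]
  attr(out, "specs") <- attr(leaderboard, "specs")[seq_len(n)]
  out
}

#' Holdout validation of one model spec
#'
#' Splits surveys into a random training share and a holdout share, fits on
#' the training surveys and returns the holdout mean DSS.
#'
#' @param data household modelling rows.
#' @param spec a [model_spec()].
#' @param train_frac training share in (0, 1) (default 0.8).
#' @param seed split seed.
#' @export
holdout_validate <- function(data, spec, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1")
  ids <- unique(data$survey_id)
  if (length(ids) < 5L) stop("need at least 5 surveys for a holdout split")
  train_ids <- with_seed(seed,
    sample(ids, max(1L, min(length(ids) - 1L, round(train_frac * length(ids))))))
  fit <- fit_quasipoisson(data[data$survey_id %in% train_ids, , drop = FALSE],
                          spec)
  dss_score(fit, data[!data$survey_id %in% train_ids, , drop = FALSE])
}

#' Select the final model from a shortlist
#'
#' Real-data applications of this workflow pick manually among the
#' shortlisted models; here
#' a deterministic default rule stands in: lowest holdout DSS, ties broken
#' by fewer parameters then lexicographic spec.  The applied rule is
#' recorded on the result.
#'
#' @param short a [shortlist()] with specs attached.
#' @param data household modelling rows.
#' @param train_frac,seed holdout settings.
#' @return the chosen [model_spec()]; the decision table in
#'   `attr(, "table")` and the rule in `attr(, "rule")`.
#' @export
select_model <- function(short, data, train_frac = 0.8, seed = 1L) {
  specs <- attr(short, "specs")
  hd <- vapply(specs, function(sp)
    holdout_validate(data, sp, train_frac, seed), 0)
  tab <- cbind(short, holdout_dss = hd)
  pick <- order(hd, short$n_terms, short$spec_id)[1L]
  structure(specs[[pick]], table = tab,
            rule = "lowest holdout DSS, then fewest parameters")
}

#' Household modelling rows for a set of surveys
#'
#' Joins each survey's canonical household table to its recall-averaged,
#' lag-shifted predictor term values (continuous values averaged over the
#' recall window, then categorized), producing the rows
#' [fit_quasipoisson()] consumes.  Cluster ids are made unique across
#' surveys.
#'
#' @param surveys list of [survey_dataset()]s.
#' @param predictors wide continuous predictor panel (`district`, `ym`,
#'   term columns).
#' @param districts district table with `district` and `admin_level`.
#' @param schemes term schemes (default [default_term_schemes()]).
#' @return data.frame of household rows with encoded term factor columns.
#' @export
survey_model_data <- function(surveys, predictors, districts,
                              schemes = default_term_schemes()) {
  rows <- lapply(surveys, function(s) {
    hh <- survey_households(s)
    tv <- survey_term_values(predictors, districts, s$meta$district,
                             s$meta$recall_start, s$meta$recall_end, schemes)
    enc <- encode_terms(tv, schemes)
    out <- data.frame(survey_id = s$meta$survey_id,
                      district = s$meta$district,
                      cluster_id = paste(s$meta$survey_id, hh$cluster, sep = ":"),
                      hh[, c("household", "pd", "pd_u5", "deaths", "deaths_u5")],
                      stringsAsFactors = FALSE)
    for (nm in setdiff(names(enc), "district")) out[[nm]] <- enc[[nm]]
    for (nm in setdiff(names(tv), c("district", "admin_level")))
      out[[paste0(nm, "_value")]] <- tv[[nm]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
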