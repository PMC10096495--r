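#' Screen predictors for completeness
#'
#' A predictor is retained when the share of district-months carrying a
#' non-missing value is at least `coverage_threshold` (inclusive).  For
#' composite predictors assembled from sub-series, `cell_threshold` is the
#' minimum share of sub-series that must be present for a cell to count as
#' observed; pass the per-cell share matrix via the optional
#' `cell_share` attribute of the raw column.
#'
#' @param raw long data.frame with columns `district`, `ym`, `predictor`,
#'   `value`.
#' @param cell_threshold per-cell completeness threshold for composite
#'   predictors (default 0.70).
#' @param coverage_threshold minimum share of district-months observed
#'   (default 0.70, inclusive).
#' @return character vector of retained predictor names; coverage shares in
#'   `attr(, "coverage")`.
#' @export
screen_completeness <- function(raw, cell_threshold = 0.70,
                                coverage_threshold = 0.70) {
  cells <- length(unique(raw$district)) * length(unique(raw$ym))
  preds <- unique(raw$predictor)
  cover <- vapply(preds, function(p) {
    sub <- raw[raw$predictor == p, , drop = FALSE]
    share <- if (!is.null(sub$cell_share)) {
      sum(!is.na(sub$value) & sub$cell_share >= cell_threshold)
    } else sum(!is.na(sub$value))
    share / cells
  }, 0)
  keep <- preds[cover >= coverage_threshold]
  attr(keep, "coverage") <- stats::setNames(cover, preds)
  keep
}

#' Spatially weighted imputation of one month's district values
#'
#' Missing districts receive a weighted mean of that month's observed
#' values, with weight `w_in` (default 1) for districts in the same region
#' and `w_out` (default 0.3) for districts outside it.  Observed cells are
#' never altered; a month with no observed value anywhere stays missing.
#'
#' @param values named numeric vector, district -> value (NA = missing).
#' @param region named character vector, district -> region.
#' @param w_in,w_out relative weights (defaults 1.0 and 0.3).
#' @return completed named vector; imputed positions flagged in
#'   `attr(, "imputed")`.
#' @export
impute_spatial <- function(values, region, w_in = 1.0, w_out = 0.3) {
  obs <- !is.na(values)
  if (!any(obs)) {
    attr(values, "imputed") <- character()
    return(values)
  }
  out <- values
  miss <- names(values)[!obs]
  for (d in miss) {
    w <- ifelse(region[names(values)[obs]] == region[[d]], w_in, w_out)
    out[[d]] <- sum(w * values[obs]) / sum(w)
  }
  attr(out, "imputed") <- miss
  out
}

#' Smooth a monthly series with a penalized cubic spline
#'
#' Wraps [stats::smooth.spline()] with a fixed smoothing knob (`spar`,
#' default 0.3).  Constants and straight lines are reproduced exactly (they
#' incur no roughness penalty).  Series shorter than 4 points pass through
#' unchanged with a warning.
#'
#' @param series numeric vector ordered by month (no NA).
#' @param smoothness smoothing parameter in `[0, 1]`; larger = smoother.
#' @return smoothed numeric vector at the same months.
#' @export
smooth_series <- function(series, smoothness = 0.3) {
  if (sum(!is.na(series)) < 4L) {
    warning("fewer than 4 points; returning series unsmoothed")
    return(series)
  }
  x <- seq_along(series)
  fit <- stats::smooth.spline(x[!is.na(series)], series[!is.na(series)],
                              spar = smoothness)
  stats::predict(fit, x)$y
}

#' Events per 100,000 person-months
#' @param count event count.
#' @param population person denominator (> 0).
#' @param scale rate scale (default 100,000).
#' @export
to_rate <- function(count, population, scale = 1e5) {
  if (any(population <= 0)) stop("population must be positive")
  count / population * scale
}

#' Lag a predictor column within districts
#'
#' The lag-`k` value at `(district, t)` is the raw value at
#' `(district, t - k)`; the leading `k` months per district are NA.
#'
#' @param panel wide data.frame with `district`, `ym` and predictor columns.
#' @param predictor column name to lag.
#' @param lag months of lag, 0..6.
#' @return the panel with an added `<predictor>_lag<k>` column (lag 0
#'   returns the panel unchanged).
#' @export
build_lags <- function(panel, predictor, lag) {
  if (!lag %in% 0:6) stop("lag must lie in 0..6 months")
  if (lag == 0L) return(panel)
  key <- paste(panel$district, panel$ym)
  src <- paste(panel$district, panel$ym - lag)
  panel[[paste0(predictor, "_lag", lag)]] <-
    panel[[predictor]][match(src, key)]
  panel
}

#' Day-weighted predictor means over a recall window
#'
#' Averages each predictor column over the calendar months a recall window
#' intersects, weighting by the number of recall days falling in each
#' month.  Predictors destined for categorization are averaged on this
#' continuous scale and cut afterwards.
#'
#' @param panel wide data.frame with `district`, `ym` and numeric columns.
#' @param district district to average in.
#' @param recall_start,recall_end recall window endpoints (`Date`).
#' @return named numeric vector of per-predictor means.
#' @export
average_over_recall <- function(panel, district, recall_start, recall_end) {
  w <- recall_month_weights(recall_start, recall_end)
  sub <- panel[panel$district == district & panel$ym %in% w$ym, , drop = FALSE]
  if (!nrow(sub)) stop("recall window does not overlap the panel")
  wts <- w$days[match(sub$ym, w$ym)]
  cols <- setdiff(names(sub), c("district", "ym", "month"))
  cols <- cols[vapply(sub[cols], is.numeric, TRUE)]
  vapply(cols, function(cl) sum(sub[[cl]] * wts) / sum(wts), 0)
}

#' Prepare the district-month predictor panel
#'
#' Runs the full preparation chain on raw long-format predictor data:
#' completeness screening, per-month spatial imputation of missing cells,
#' optional spline smoothing of price-type series, per-capita rate scaling,
#' and lag construction.  Returns the wide analysis panel plus a provenance
#' flag per cell (`observed` / `imputed`).
#'
#' @param raw long data.frame (`district`, `ym`, `predictor`, `value`).
#' @param region named character vector, district -> region.
#' @param smooth character vector of predictors to smooth (e.g. prices).
#' @param lags named integer vector, predictor -> lag months to add.
#' @param smoothness spline knob (default 0.3).
#' @param w_in,w_out imputation weights (defaults 1.0 / 0.3).
#' @param cell_threshold,coverage_threshold completeness rule (0.70 / 0.70).
#' @return list: `panel` (wide data.frame), `provenance` (long data.frame),
#'   `retained` (predictor names kept by the completeness screen).
#' @export
prepare_panel <- function(raw, region, smooth = character(),
                          lags = c(sam = 2L), smoothness = 0.3,
                          w_in = 1.0, w_out = 0.3,
                          cell_threshold = 0.70, coverage_threshold = 0.70) {
  retained <- screen_completeness(raw, cell_threshold, coverage_threshold)
  raw <- raw[raw$predictor %in% retained, , drop = FALSE]
  districts <- sort(unique(raw$district))
  months <- sort(unique(raw$ym))
  panel <- expand.grid(district = districts, ym = months,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prov <- list()
  for (p in retained) {
    sub <- raw[raw$predictor == p, , drop = FALSE]
    v <- sub$value[match(paste(panel$district, panel$ym),
                         paste(sub$district, sub$ym))]
    flag <- ifelse(is.na(v), "missing", "observed")
    # impute month by month
    for (m in months) {
      i <- panel$ym == m
      vm <- stats::setNames(v[i], panel$district[i])
      if (anyNA(vm) && any(!is.na(vm))) {
        filled <- impute_spatial(vm, region, w_in, w_out)
        flag[i][is.na(vm)] <- "imputed"
        v[i] <- as.numeric(filled)
      }
    }
    if (p %in% smooth) {
      for (d in districts) {
        i <- panel$district == d
        if (all(!is.na(v[i]))) v[i] <- smooth_series(v[i][order(panel$ym[i])],
                                                     smoothness)
      }
      flag[flag == "observed"] <- "smoothed"
    }
    panel[[p]] <- v
    prov[[p]] <- data.frame(district = panel$district, ym = panel$ym,
                            predictor = p, provenance = flag,
                            stringsAsFactors = FALSE)
  }
  for (p in names(lags)) {
    if (p %in% names(panel)) panel <- build_lags(panel, p, lags[[p]])
  }
  list(panel = panel, provenance = do.call(rbind, prov), retained = retained)
}
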