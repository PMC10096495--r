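#' A census-source population anchor
#'
#' One alternative census estimate: a per-district population snapshot
#' centred on a month, with a 0-1 quality score used later as an averaging
#' weight.
#'
#' @param source source name.
#' @param ym anchor month (`"YYYY-MM"` or index).
#' @param population named numeric vector, district -> population (> 0).
#' @param quality quality score in `[0, 1]`.
#' @param bias optional true multiplicative bias (synthetic anchors only).
#' @export
census_anchor <- function(source, ym, population, quality, bias = NA_real_) {
  ym <- ym(ym)
  if (any(population <= 0)) stop("anchor populations must be positive")
  if (quality < 0 || quality > 1) stop("quality score must lie in [0, 1]")
  if (is.null(names(population))) stop("population must be named by district")
  structure(list(source = source, ym = ym, population = population,
                 quality = quality, bias = bias), class = "census_anchor")
}

#' Project one census anchor into a monthly population series
#'
#' Applies a monthly growth factor `g = (1 + growth_rate_yr)^(1/12)` and
#' monthly net displacement/refugee flows, forward and backward from the
#' anchor month: forward `P[t+1] = g * P[t] + net[t+1]`; backward uses the
#' exact algebraic inverse `P[t-1] = (P[t] - net[t]) / g`, so a round trip
#' reproduces the anchor to round-off.  The series is floored at `floor`
#' (default 1 person); months where the floor binds are counted in
#' `attr(, "floored")` as a data-quality warning.
#'
#' @param anchor a [census_anchor()].
#' @param growth_rate_yr yearly natural growth rate (proportion).
#' @param flows flow data.frame (`ym`, `origin`, `destination`, `persons`,
#'   `reason`, `kind`), or NULL.
#' @param month_range inclusive month endpoints (`"YYYY-MM"` or indices).
#' @param floor minimum population.
#' @return district x month population matrix.
#' @export
project_source <- function(anchor, growth_rate_yr, flows, month_range,
                           floor = 1) {
  stopifnot(inherits(anchor, "census_anchor"))
  months <- ym_seq(month_range[1], month_range[2])
  ext <- seq.int(min(months[1], anchor$ym), max(months[length(months)], anchor$ym))
  districts <- names(anchor$population)
  g <- (1 + growth_rate_yr)^(1 / 12)
  net <- net_flow_matrix(districts, ext, flows)
  pop <- matrix(NA_real_, length(districts), length(ext),
                dimnames = list(districts, ym_format(ext)))
  j0 <- match(anchor$ym, ext)
  pop[, j0] <- anchor$population
  n_floor <- 0L
  if (j0 < length(ext)) for (j in (j0 + 1L):length(ext)) {
    p <- g * pop[, j - 1L] + net[, j]
    n_floor <- n_floor + sum(p < floor)
    pop[, j] <- pmax(floor, p)
  }
  if (j0 > 1L) for (j in (j0 - 1L):1L) {
    p <- (pop[, j + 1L] - net[, j + 1L]) / g
    n_floor <- n_floor + sum(p < floor)
    pop[, j] <- pmax(floor, p)
  }
  out <- pop[, ym_format(months), drop = FALSE]
  attr(out, "floored") <- n_floor
  out
}

#' Quality-weighted average of per-source population series
#'
#' Weights are the sources' quality scores normalised to sum to one; the
#' combined series is the per-cell weighted arithmetic mean.
#'
#' @param series list of district x month matrices (identical dimnames).
#' @param weights per-source quality scores (not all zero).
#' @return district x month matrix.
#' @export
combine_sources <- function(series, weights) {
  stopifnot(length(series) >= 1L, length(weights) == length(series))
  if (all(weights == 0)) stop("all-zero source weights")
  w <- weights / sum(weights)
  out <- series[[1]] * w[1]
  for (i in seq_along(series)[-1L]) out <- out + series[[i]] * w[i]
  out
}

#' Displacement totals and shares by reported reason
#'
#' Sums displaced/returned persons by reason over internal movement kinds
#' (IDP and returnee; refugee legs are excluded) and reports each reason's
#' share of the total, rounded to 0.1%.
#'
#' @param flows flow data.frame.
#' @param kinds movement kinds counted (default IDP + returnee).
#' @return data.frame with `reason`, `persons`, `share_pct`; zero total
#'   gives an empty frame with a warning.
#' @export
displacement_summary <- function(flows, kinds = c("IDP", "returnee")) {
  f <- flows[flows$kind %in% kinds, , drop = FALSE]
  tot <- tapply(f$persons, f$reason, sum)
  tot <- tot[!is.na(tot) & tot > 0]
  if (!length(tot) || sum(tot) == 0) {
    warning("no displacement recorded; shares undefined")
    return(data.frame(reason = character(), persons = numeric(),
                      share_pct = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(reason = names(tot), persons = as.numeric(tot),
                    share_pct = round(100 * as.numeric(tot) / sum(tot), 1),
                    stringsAsFactors = FALSE)
  out[order(-out$persons), ]
}

#' Reconstruct district-month population denominators
#'
#' Projects every census anchor across the month range with growth and
#' flows ([project_source()]), averages the sources by quality weight
#' ([combine_sources()]), applies a single global under-5 fraction, and
#' accumulates IDP/returnee arrivals into a displaced-population
#' proportion.
#'
#' @param anchors list of [census_anchor()]s.
#' @param flows flow data.frame.
#' @param month_range inclusive month endpoints.
#' @param growth_rate_yr yearly growth rate (default 0.021).
#' @param under5_fraction proportion of the population under 5
#'   (default 0.250).
#' @param floor population floor.
#' @return object of class `population_series`: list with `months`,
#'   `districts`, matrices `pop`, `pop_u5`, `prop_idp`, and the per-source
#'   series in `by_source`.
#' @export
build_population_series <- function(anchors, flows, month_range,
                                    growth_rate_yr = 0.021,
                                    under5_fraction = 0.250, floor = 1) {
  months <- ym_seq(month_range[1], month_range[2])
  by_source <- lapply(anchors, project_source, growth_rate_yr = growth_rate_yr,
                      flows = flows, month_range = months[c(1L, length(months))],
                      floor = floor)
  names(by_source) <- vapply(anchors, function(a) a$source, "")
  weights <- vapply(anchors, function(a) a$quality, 0)
  pop <- combine_sources(by_source, weights)
  districts <- rownames(pop)
  # displaced stock: cumulated IDP/returnee arrivals over the range
  stock <- matrix(0, length(districts), length(months),
                  dimnames = dimnames(pop))
  f <- flows[flows$kind %in% c("IDP", "returnee") & !is.na(flows$destination) &
               flows$ym %in% months, , drop = FALSE]
  if (nrow(f)) {
    inflow <- matrix(0, length(districts), length(months),
                     dimnames = dimnames(pop))
    idx <- cbind(match(f$destination, districts), match(f$ym, months))
    for (k in seq_len(nrow(f)))
      inflow[idx[k, 1L], idx[k, 2L]] <- inflow[idx[k, 1L], idx[k, 2L]] + f$persons[k]
    stock <- t(apply(inflow, 1L, cumsum))
  }
  structure(list(months = months, districts = districts, pop = pop,
                 pop_u5 = pop * under5_fraction,
                 prop_idp = pmin(stock / pop, 1),
                 by_source = by_source,
                 under5_fraction = under5_fraction),
            class = "population_series")
}

#' @export
print.population_series <- function(x, ...) {
  cat("<population_series>", length(x$districts), "districts x",
      length(x$months), "months;", length(x$by_source), "sources; total",
      format(round(sum(x$pop[, ncol(x$pop)])), big.mark = ","),
      "at", ym_format(x$months[length(x$months)]), "\n")
  invisible(x)
}

#' @export
as.data.frame.population_series <- function(x, ...) {
  grid <- expand.grid(district = x$districts, ym = x$months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(grid$district, x$districts), match(grid$ym, x$months))
  data.frame(grid, month = ym_format(grid$ym), pop = x$pop[idx],
             pop_u5 = x$pop_u5[idx], prop_idp = x$prop_idp[idx],
             stringsAsFactors = FALSE)
}
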