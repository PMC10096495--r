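#' Category scheme for a continuous predictor
#'
#' Mortality predictors enter the models as ordered categories cut from a
#' continuous per-capita rate.  Intervals are half-open and lower-inclusive:
#' a value equal to a cut-point belongs to the level above it (0.25 falls in
#' "0.25-0.49", 0.50 in ">=0.50").  The lowest level is the reference.
#'
#' @param name predictor name.
#' @param cuts strictly increasing cut-points.
#' @param labels level labels, `length(cuts) + 1`, lowest first.
#' @param lag lag in months applied before joining to outcomes (0..6).
#' @return an object of class `category_scheme`.
#' @examples
#' sch <- category_scheme("conflict", c(0.25, 0.5),
#'                        c("<0.25", "0.25-0.49", ">=0.50"))
#' categorize(c(0.1, 0.25, 0.6), sch)
#' @export
category_scheme <- function(name, cuts, labels, lag = 0L) {
  stopifnot(is.character(name), length(cuts) >= 1L,
            all(diff(cuts) > 0), length(labels) == length(cuts) + 1L,
            lag %in% 0:6)
  structure(list(name = name, cuts = as.numeric(cuts),
                 labels = as.character(labels), lag = as.integer(lag)),
            class = "category_scheme")
}

#' Assign categorical levels to continuous values
#'
#' @param value numeric vector.
#' @param scheme a [category_scheme()].
#' @return factor with the scheme's levels (lowest = reference).
#' @export
categorize <- function(value, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (any(!is.finite(value) & !is.na(value)))
    stop("non-finite value passed to categorize()")
  idx <- findInterval(value, scheme$cuts) + 1L  # lower-inclusive half-open
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Default predictor term schemes
#'
#' The term set used throughout: administrative level (a static factor), and
#' four categorized incidence rates per 100,000 person-months — armed
#' conflict events, severe acute malnutrition (SAM) treatment admissions
#' (lagged 2 months), health-facility malaria cases, and reported measles
#' cases (any vs none).  SAM cut-points are configuration defaults of 100
#' and 200 admissions per 100,000 person-months.
#'
#' @return named list of term definitions; categorized terms carry a
#'   `category_scheme`, factor terms their level set.
#' @export
default_term_schemes <- function() {
  list(
    admin_level = list(type = "factor",
                       levels = c("somaliland_puntland", "south_central")),
    conflict = list(type = "categorical",
                    scheme = category_scheme("conflict", c(0.25, 0.50),
                                             c("<0.25", "0.25-0.49", ">=0.50"))),
    sam = list(type = "categorical",
               scheme = category_scheme("sam", c(100, 200),
                                        c("<100", "100-199", ">=200"),
                                        lag = 2L)),
    malaria = list(type = "categorical",
                   scheme = category_scheme("malaria", c(1, 50),
                                            c("0", "1-49", ">=50"))),
    measles = list(type = "categorical",
                   scheme = category_scheme("measles", 1e-9, c("0", ">0")))
  )
}

#' Default true log rate ratios for the synthetic world
#'
#' Named per term and non-reference level, on the log scale.  Values mirror
#' the crude-death-rate rate ratios of the final Somalia model (conflict
#' >= 0.50: 1.60; SAM categories 1.36 and 1.48; malaria 0.78 and 0.71;
#' measles > 0: 1.27; south-central administrative level 0.97), so the
#' generator's truth is a realistic effect structure that downstream model
#' fitting should recover.
#'
#' @return named list: term -> named numeric vector over non-reference levels.
#' @export
default_true_coefficients <- function() {
  list(
    admin_level = c(south_central = log(0.97)),
    conflict = c("0.25-0.49" = log(1.00), ">=0.50" = log(1.60)),
    sam = c("100-199" = log(1.36), ">=200" = log(1.48)),
    malaria = c("1-49" = log(0.78), ">=50" = log(0.71)),
    measles = c(">0" = log(1.27))
  )
}

# Encode a data.frame of continuous predictor columns (plus admin_level)
# into the factor columns the models use.  `lagged` columns are expected to
# be pre-lagged; this only cuts/levels them.
encode_terms <- function(df, schemes = default_term_schemes()) {
  out <- df
  for (nm in names(schemes)) {
    defn <- schemes[[nm]]
    if (!nm %in% names(df)) next
    if (defn$type == "factor") {
      out[[nm]] <- factor(df[[nm]], levels = defn$levels)
    } else {
      out[[nm]] <- categorize(df[[nm]], defn$scheme)
    }
  }
  out
}

# Linear predictor contribution of encoded term columns under a coefficient
# map (term -> named vector over non-reference levels).  Reference levels and
# terms without coefficients contribute 0.
linpred_terms <- function(encoded, coefficients) {
  lp <- numeric(nrow(encoded))
  for (nm in names(coefficients)) {
    if (!nm %in% names(encoded))
      stop("coefficient references unknown predictor term: ", nm)
    cf <- coefficients[[nm]]
    lev <- as.character(encoded[[nm]])
    hit <- match(lev, names(cf))
    lp <- lp + ifelse(is.na(hit), 0, cf[hit])
  }
  lp
}
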