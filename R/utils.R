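#' @keywords internal
"_PACKAGE"

#' Calendar-month index helpers
#'
#' District-month panels are keyed by an integer month index
#' `ym = 12 * year + (month - 1)` so that lags, ranges and differences are
#' plain integer arithmetic.  `ym()` parses `"YYYY-MM"` strings,
#' `ym_format()` inverts it, `ym_seq()` builds an inclusive range.
#'
#' @param x character vector of `"YYYY-MM"` strings (for `ym()`), or an
#'   integer month index (for the other helpers).
#' @return integer month indices, or their year / month-of-year / string
#'   representation.
#' @examples
#' ym("2014-01")
#' ym_format(ym("2017-06") + 7)
#' @export
ym <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("not a 'YYYY-MM' month: ", paste(x[bad], collapse = ", "))
  yr <- as.integer(vapply(m, `[`, "", 2L))
  mo <- as.integer(vapply(m, `[`, "", 3L))
  if (any(mo < 1L | mo > 12L)) stop("month-of-year outside 1..12")
  12L * yr + (mo - 1L)
}

#' @rdname ym
#' @export
ym_year <- function(x) as.integer(x) %/% 12L

#' @rdname ym
#' @export
ym_month <- function(x) as.integer(x) %% 12L + 1L

#' @rdname ym
#' @export
ym_format <- function(x) sprintf("%04d-%02d", ym_year(x), ym_month(x))

#' @param from,to inclusive endpoints, as `"YYYY-MM"` or integer indices.
#' @rdname ym
#' @export
ym_seq <- function(from, to) {
  from <- ym(from); to <- ym(to)
  if (to < from) stop("empty month range")
  seq.int(from, to)
}

#' @rdname ym
#' @export
ym_days <- function(x) {
  # days in the calendar month
  yr <- ym_year(x); mo <- ym_month(x)
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[mo]
  leap <- (yr %% 4L == 0L & yr %% 100L != 0L) | yr %% 400L == 0L
  ifelse(mo == 2L & leap, 29L, dm)
}

#' First day of a month as a Date
#' @param x integer month index or `"YYYY-MM"`.
#' @return `Date` vector (first of the month).
#' @export
ym_date <- function(x) {
  x <- ym(x)
  as.Date(sprintf("%04d-%02d-01", ym_year(x), ym_month(x)))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables here round half up
#' (44,650 -> 44,700 at the nearest hundred).
#'
#' @param x numeric vector.
#' @param to rounding unit (100 for report tables).
#' @export
round_half_up <- function(x, to = 1) {
  sign(x) * floor(abs(x) / to + 0.5) * to
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stage seed from the master seed
#'
#' One master seed fans out to per-stage seeds so stages can be re-run
#' standalone yet reproduce the orchestrated run.  The derivation hashes the
#' stage name into an offset; results stay below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name (character scalar).
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 99991L
  as.integer((abs(as.numeric(master)) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
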