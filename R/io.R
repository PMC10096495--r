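#' Write the canonical input CSV schemas
#'
#' Serialises a synthetic world and its surveys into the four plain-text
#' input families any run of the pipeline can start from:
#' `surveys_meta.csv` (one row per survey), `survey_members.csv`
#' (individual-questionnaire member listings) and `survey_households.csv`
#' (aggregate-questionnaire totals), `census_anchors.csv` (long: source,
#' month, district, population, quality), `displacement_flows.csv` (month,
#' origin, destination, persons, reason, kind), `predictors_raw.csv` (long:
#' district, month, predictor, value), plus `world_config.yaml` with the
#' scalar configuration.
#'
#' @param world a `synthetic_world`.
#' @param surveys list of [survey_dataset()]s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world_csvs <- function(world, surveys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)

  meta <- do.call(rbind, lapply(surveys, function(s)
    data.frame(survey_id = s$meta$survey_id, district = s$meta$district,
               universe = s$meta$universe, design = s$meta$design,
               recall_start = as.character(s$meta$recall_start),
               recall_end = as.character(s$meta$recall_end),
               questionnaire = s$meta$questionnaire,
               frame_clear = s$meta$frame_clear,
               standard_questionnaire = s$meta$standard_questionnaire,
               stringsAsFactors = FALSE)))
  w(meta, "surveys_meta.csv")

  members <- do.call(rbind, lapply(surveys, function(s) {
    if (is.null(s$members)) return(NULL)
    data.frame(survey_id = s$meta$survey_id, s$members,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(members)) {
    members$entry <- as.character(members$entry)
    members$exit <- as.character(members$exit)
    w(members, "survey_members.csv")
  }
  households <- do.call(rbind, lapply(surveys, function(s) {
    if (is.null(s$households)) return(NULL)
    data.frame(survey_id = s$meta$survey_id, s$households,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(households)) w(households, "survey_households.csv")

  anchors <- do.call(rbind, lapply(world$anchors, function(a)
    data.frame(source = a$source, month = ym_format(a$ym),
               district = names(a$population),
               population = as.numeric(a$population), quality = a$quality,
               stringsAsFactors = FALSE)))
  w(anchors, "census_anchors.csv")

  flows <- world$flows
  flows$month <- ym_format(flows$ym)
  w(flows[, c("month", "origin", "destination", "persons", "reason", "kind")],
    "displacement_flows.csv")

  value_cols <- setdiff(names(world$predictors), c("district", "ym"))
  raw <- do.call(rbind, lapply(value_cols, function(p)
    data.frame(district = world$predictors$district,
               month = ym_format(world$predictors$ym), predictor = p,
               value = world$predictors[[p]], stringsAsFactors = FALSE)))
  w(raw, "predictors_raw.csv")
  w(world$districts, "districts.csv")

  cfg <- world$config
  yaml::write_yaml(list(
    n_districts = cfg$n_districts, n_regions = cfg$n_regions,
    month_range = ym_format(cfg$month_range),
    baseline_cdr = cfg$baseline_cdr, baseline_u5dr = cfg$baseline_u5dr,
    growth_rate_yr = cfg$growth_rate_yr,
    under5_fraction = cfg$under5_fraction,
    crisis_window = ym_format(cfg$crisis_window), seed = cfg$seed),
    file.path(dir, "world_config.yaml"))
  invisible(dir)
}

#' Read surveys back from the canonical CSV schemas
#'
#' @param dir directory written by [write_world_csvs()].
#' @return list of [survey_dataset()]s.
#' @export
read_surveys_csv <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "surveys_meta.csv"),
                          stringsAsFactors = FALSE)
  mem_path <- file.path(dir, "survey_members.csv")
  hh_path <- file.path(dir, "survey_households.csv")
  members <- if (file.exists(mem_path))
    utils::read.csv(mem_path, stringsAsFactors = FALSE) else NULL
  households <- if (file.exists(hh_path))
    utils::read.csv(hh_path, stringsAsFactors = FALSE) else NULL
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    sm <- survey_meta(m$survey_id, m$district, m$universe, m$design,
                      as.Date(m$recall_start), as.Date(m$recall_end),
                      m$questionnaire, m$frame_clear,
                      m$standard_questionnaire)
    if (m$questionnaire == "individual") {
      mm <- members[members$survey_id == m$survey_id, -1L]
      mm$entry <- as.Date(mm$entry); mm$exit <- as.Date(mm$exit)
      survey_dataset(sm, members = mm)
    } else {
      survey_dataset(sm,
                     households = households[households$survey_id == m$survey_id, -1L])
    }
  })
}

#' Read census anchors from CSV
#' @param path `census_anchors.csv` file path.
#' @return list of [census_anchor()]s.
#' @export
read_anchors_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$source), function(s)
    census_anchor(s$source[1], s$month[1],
                  stats::setNames(s$population, s$district), s$quality[1]))
}

#' Read displacement flows from CSV
#' @param path `displacement_flows.csv` file path.
#' @return flow data.frame with integer `ym` month index.
#' @export
read_flows_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$ym <- ym(df$month)
  df$destination[df$destination %in% c("", "NA")] <- NA_character_
  df[, c("ym", "origin", "destination", "persons", "reason", "kind")]
}

#' Read a long-format raw predictor file
#' @param path `predictors_raw.csv` file path.
#' @return long data.frame with `district`, `ym`, `predictor`, `value`.
#' @export
read_predictors_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$ym <- ym(df$month)
  df[, c("district", "ym", "predictor", "value")]
}
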