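# Small memoised fixtures so independent tests can share one generated
# world without re-simulating it.

.fixture_cache <- new.env(parent = emptyenv())

tiny_world <- function(seed = 99L, n_districts = 6L, n_regions = 3L, ...) {
  key <- paste("world", seed, n_districts, n_regions, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_world(
      world_config(n_districts = n_districts, n_regions = n_regions,
                   seed = seed, ...))
  .fixture_cache[[key]]
}

tiny_surveys <- function(world = tiny_world(), n = 12L, seed = 7L, ...) {
  key <- paste("svy", world$config$seed, n, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_surveys(world, n, seed = seed, ...)
  .fixture_cache[[key]]
}

all_terms <- function() c("admin_level", "conflict", "sam", "malaria", "measles")

tiny_model_data <- function() {
  key <- "model_data"
  if (is.null(.fixture_cache[[key]])) {
    w <- tiny_world()
    .fixture_cache[[key]] <-
      survey_model_data(tiny_surveys(w, 14), w$predictors, w$districts)
  }
  .fixture_cache[[key]]
}

# A one-survey dataset with fully known counts for closed-form checks.
handmade_survey <- function(deaths = c(1, 1, 0, 0), pd = c(10000, 10000, 10000, 10000),
                            clusters = c("c1", "c1", "c2", "c2")) {
  meta <- survey_meta("hand01", "dX", design = "cluster",
                      recall_start = as.Date("2017-01-01"),
                      recall_end = as.Date("2017-04-10"),
                      questionnaire = "aggregate")
  recall_days <- as.numeric(meta$recall_end - meta$recall_start) + 1
  # aggregate rows engineered so derived person-time equals `pd` exactly
  n_end <- pd / recall_days - 0.5 * deaths
  hh <- data.frame(household = sprintf("hh%02d", seq_along(deaths)),
                   cluster = clusters, n_end = n_end, u5_end = n_end / 2,
                   births = 0, joins = 0, leaves = 0,
                   deaths = deaths, deaths_u5 = 0)
  survey_dataset(meta, households = hh)
}
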