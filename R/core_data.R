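## Data model and validated I/O for census, plant, and site tables.
##
## Conventions: time is decimal years on a quarterly grid
## (x.00 / x.25 / x.50 / x.75); quadrats are 5 x 2 m (10 m^2) sampling
## units nested in four transects per site; adults are plants with >= 4
## stipes, pre-adults have branched and are taller than 1 m, juveniles are
## all earlier stages.

## Census table column groups
.census_keys   <- c("site_id", "transect_id", "quadrat_id", "date")
.census_counts <- c("macro_adult", "macro_preadult", "macro_juvenile",
                    "stipe_count", "stipitate", "laminate", "desmarestia")
.census_covers <- c("brown_turf", "red_turf", "articulated_coralline",
                    "cystoseira")
.census_urchin <- c("psu_density", "rsu_density")
.census_cols <- c(.census_keys, .census_counts, .census_covers, .census_urchin)

#' Validate a quadrat census table
#'
#' Checks the invariants of the census data model: required columns, counts
#' non-negative, fractional covers in \[0, 1\], urchin densities
#' non-negative, and uniqueness of (site, transect, quadrat, date).
#'
#' @param census a data frame with the census columns (see [load_census()]).
#' @return the validated data frame, sorted by (site, date, transect,
#'   quadrat), invisibly classed `kelp_census`.
#' @export
validate_census <- function(census) {
  missing <- setdiff(.census_cols, names(census))
  if (length(missing))
    stopf("census table is missing columns: %s", paste(missing, collapse = ", "))
  census$date <- decimal_year(census$date)
  for (col in c(.census_counts, .census_urchin)) {
    bad <- which(!is.finite(census[[col]]) | census[[col]] < 0)
    if (length(bad))
      stopf("census row %d: field '%s' is negative or non-finite (%s)",
            bad[1], col, format(census[[col]][bad[1]]))
  }
  for (col in .census_covers) {
    bad <- which(!is.finite(census[[col]]) | census[[col]] < 0 | census[[col]] > 1)
    if (length(bad))
      stopf("census row %d: field '%s' outside [0, 1] (%s)",
            bad[1], col, format(census[[col]][bad[1]]))
  }
  key <- paste(census$site_id, census$transect_id, census$quadrat_id,
               format(census$date, nsmall = 2))
  if (anyDuplicated(key))
    stopf("census row %d: duplicate (site, transect, quadrat, date) key '%s'",
          which(duplicated(key))[1], key[which(duplicated(key))[1]])
  ord <- order(census$site_id, census$date, census$transect_id, census$quadrat_id)
  census <- census[ord, , drop = FALSE]
  rownames(census) <- NULL
  class(census) <- unique(c("kelp_census", class(census)))
  census
}

#' Read a quadrat census table from CSV
#'
#' One row per quadrat per census date. Expected columns: `site_id`,
#' `transect_id` (1-4), `quadrat_id` (1-10), `date` (decimal years or ISO
#' dates), per-quadrat counts `macro_adult`, `macro_preadult`,
#' `macro_juvenile`, `stipe_count`, `stipitate`, `laminate`, `desmarestia`,
#' fractional covers `brown_turf`, `red_turf`, `articulated_coralline`,
#' `cystoseira`, and urchin densities `psu_density`, `rsu_density`
#' (individuals m^-2; purple and red sea urchins).
#'
#' @param path CSV file path.
#' @return a validated `kelp_census` data frame sorted by
#'   (site, date, transect, quadrat).
#' @export
load_census <- function(path) {
  census <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_census(census)
}

#' Write a census table to CSV
#' @param census a census data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  utils::write.csv(as.data.frame(census)[, .census_cols], path, row.names = FALSE)
  invisible(path)
}

#' Assemble a plant table from components
#'
#' Internal constructor shared by the readers and the simulator. The stipe
#' series is a list of `data.frame(date, stipes)`, one per plant, ordered
#' in time.
#'
#' @param plant_id,site_id,quadrat_id identifiers.
#' @param recruit_date,last_date decimal years (first/last census observed
#'   as an adult).
#' @param dead logical; `FALSE` means right-censored at `last_date`.
#' @param stipe_series list of per-plant `data.frame(date, stipes)`.
#' @return a `kelp_plants` data frame.
#' @export
plant_table <- function(plant_id, site_id, quadrat_id, recruit_date,
                        last_date, dead, stipe_series) {
  out <- data.frame(plant_id = as.character(plant_id),
                    site_id = as.character(site_id),
                    quadrat_id = as.character(quadrat_id),
                    recruit_date = as.numeric(recruit_date),
                    last_date = as.numeric(last_date),
                    dead = as.logical(dead),
                    cohort_id = NA_character_,
                    stringsAsFactors = FALSE)
  out$stipe_series <- stipe_series
  validate_plants(out)
}

#' Validate a plant table
#'
#' Invariants: unique plant ids; `last_date >= recruit_date`; stipe series
#' dates strictly increasing and starting at `recruit_date`; >= 4 stipes at
#' adult recruitment.
#'
#' @param plants a plant data frame (see [plant_table()]).
#' @return the validated `kelp_plants` data frame.
#' @export
validate_plants <- function(plants) {
  if (anyDuplicated(plants$plant_id))
    stopf("duplicate plant_id '%s'",
          plants$plant_id[which(duplicated(plants$plant_id))[1]])
  bad <- which(plants$last_date < plants$recruit_date)
  if (length(bad))
    stopf("plant '%s': last_date precedes recruit_date", plants$plant_id[bad[1]])
  for (i in seq_len(nrow(plants))) {
    ss <- plants$stipe_series[[i]]
    if (is.null(ss) || nrow(ss) == 0) next
    if (any(diff(ss$date) <= 0))
      stopf("plant '%s': stipe series dates not strictly increasing",
            plants$plant_id[i])
    if (ss$stipes[1] < 4)
      stopf("plant '%s': %d stipes at adult recruitment (adults have >= 4)",
            plants$plant_id[i], ss$stipes[1])
  }
  rownames(plants) <- NULL
  class(plants) <- unique(c("kelp_plants", class(plants)))
  plants
}

#' Read a plant table from CSV
#'
#' Two dialects are supported. `"long"`: one row per plant-census
#' observation with columns `plant_id`, `site_id`, `quadrat_id`, `date`,
#' `stipes`; the per-plant record is assembled by grouping, and the death
#' flag is derived — a plant absent from a later census is dead at the
#' first missed census, a plant present at its site's final census is
#' right-censored. `"wide"`: one row per plant with columns `plant_id`,
#' `site_id`, `quadrat_id`, `recruit_date`, `last_date`, `dead`, and a
#' `stipe_series` field serialized as `date:stipes` pairs joined by `;`.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param final_census optional named vector of final census dates per
#'   site; defaults to the last date seen per site in the table (long
#'   dialect only).
#' @return a validated `kelp_plants` data frame.
#' @export
load_plants <- function(path, dialect = c("long", "wide"), final_census = NULL) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (dialect == "long") {
    need <- c("plant_id", "site_id", "quadrat_id", "date", "stipes")
    missing <- setdiff(need, names(raw))
    if (length(missing))
      stopf("plant table (long) missing columns: %s", paste(missing, collapse = ", "))
    raw$date <- decimal_year(raw$date)
    raw <- raw[order(raw$plant_id, raw$date), ]
    if (is.null(final_census))
      final_census <- tapply(raw$date, raw$site_id, max)
    by_plant <- split(raw, raw$plant_id)
    ss <- lapply(by_plant, function(d)
      data.frame(date = d$date, stipes = d$stipes))
    first <- do.call(rbind, lapply(by_plant, function(d) d[1, ]))
    last_date <- vapply(by_plant, function(d) max(d$date), 0)
    dead <- last_date < (final_census[first$site_id] - 1e-9)
    plant_table(first$plant_id, first$site_id, first$quadrat_id,
                vapply(by_plant, function(d) min(d$date), 0),
                last_date, dead, unname(ss))
  } else {
    need <- c("plant_id", "site_id", "quadrat_id", "recruit_date",
              "last_date", "dead", "stipe_series")
    missing <- setdiff(need, names(raw))
    if (length(missing))
      stopf("plant table (wide) missing columns: %s", paste(missing, collapse = ", "))
    ss <- lapply(raw$stipe_series, function(s) {
      if (is.na(s) || !nzchar(s)) return(data.frame(date = numeric(), stipes = numeric()))
      parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      data.frame(date = as.numeric(vapply(parts, `[`, "", 1)),
                 stipes = as.numeric(vapply(parts, `[`, "", 2)))
    })
    plant_table(raw$plant_id, raw$site_id, raw$quadrat_id,
                decimal_year(raw$recruit_date), decimal_year(raw$last_date),
                as.logical(raw$dead), ss)
  }
}

#' Write a plant table to CSV (wide dialect)
#' @param plants a `kelp_plants` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plants <- function(plants, path) {
  ser <- vapply(plants$stipe_series, function(ss) {
    if (is.null(ss) || nrow(ss) == 0) return("")
    paste(sprintf("%s:%s", format(ss$date, trim = TRUE, nsmall = 0),
                  format(ss$stipes, trim = TRUE)), collapse = ";")
  }, "")
  out <- data.frame(plant_id = plants$plant_id, site_id = plants$site_id,
                    quadrat_id = plants$quadrat_id,
                    recruit_date = plants$recruit_date,
                    last_date = plants$last_date, dead = plants$dead,
                    stipe_series = ser)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plant lifespans with censoring flags
#'
#' Death between quarterly censuses is interval-censored; the death time is
#' resolved by `convention`: `"midpoint"` (default) places it midway
#' between the last census observed alive and the first missed census,
#' `"last-seen"` at the last observation, `"first-missed"` one census step
#' later. Right-censored plants (alive at the series end) get
#' `duration = last_date - recruit_date` and `event = FALSE`.
#'
#' @param plants a `kelp_plants` data frame.
#' @param convention death-time convention (see above).
#' @param step census step in years (quarterly grid: 0.25).
#' @return `data.frame(plant_id, duration, event)` in years.
#' @export
lifespan <- function(plants, convention = c("midpoint", "last-seen", "first-missed"),
                     step = 0.25) {
  convention <- match.arg(convention)
  offset <- switch(convention, "midpoint" = step / 2, "last-seen" = 0,
                   "first-missed" = step)
  dur <- plants$last_date - plants$recruit_date + ifelse(plants$dead, offset, 0)
  data.frame(plant_id = plants$plant_id, duration = dur, event = plants$dead)
}

#' Read site metadata
#'
#' Columns: `site_id`, `depth` (m, within 8-21), `year_established`,
#' `physiography` (free text).
#'
#' @param path CSV file path.
#' @return a data frame.
#' @export
load_site_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("site_id", "depth", "year_established")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stopf("site table missing columns: %s", paste(missing, collapse = ", "))
  bad <- which(meta$depth < 8 | meta$depth > 21)
  if (length(bad))
    stopf("site '%s': depth %.1f m outside the 8-21 m study range",
          meta$site_id[bad[1]], meta$depth[bad[1]])
  meta
}

#' Read an environment series from CSV
#'
#' Temperature series have columns `date`, `temperature` (deg C, nominally
#' 3-h cadence); wave series have `date`, `hs` (significant wave height,
#' m), `period` (s).
#'
#' @param path CSV file path.
#' @param kind `"temperature"` or `"wave"`.
#' @return a data frame with attribute `kind`, timestamps in decimal years,
#'   strictly increasing.
#' @export
load_env_series <- function(path, kind = c("temperature", "wave")) {
  kind <- match.arg(kind)
  env <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  env$date <- decimal_year(env$date)
  env <- env[order(env$date), , drop = FALSE]
  if (any(diff(env$date) <= 0)) stopf("environment series: duplicate timestamps")
  if (kind == "wave") {
    if (!all(c("hs", "period") %in% names(env)))
      stopf("wave series needs columns hs, period")
    if (any(env$hs < 0, na.rm = TRUE)) stopf("negative hs in wave series")
    if (any(env$period <= 0, na.rm = TRUE)) stopf("non-positive wave period")
  } else if (!"temperature" %in% names(env)) {
    stopf("temperature series needs column temperature")
  }
  rownames(env) <- NULL
  attr(env, "kind") <- kind
  env
}

#' @export
print.kelp_census <- function(x, ...) {
  cat(sprintf("Quadrat census table: %d records, %d site(s), %s-%s\n",
              nrow(x), length(unique(x$site_id)),
              format(min(x$date), nsmall = 2), format(max(x$date), nsmall = 2)))
  print(utils::head(as.data.frame(x)[, c(.census_keys, "macro_adult",
                                         "stipe_count", "macro_juvenile")]), ...)
  invisible(x)
}

#' @export
print.kelp_plants <- function(x, ...) {
  cat(sprintf("Plant table: %d plants, %d site(s), %d dead / %d censored\n",
              nrow(x), length(unique(x$site_id)), sum(x$dead), sum(!x$dead)))
  invisible(x)
}
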