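## Cohort demography: detection of adult-recruitment windows, plant
## assignment, pulsed/trickled classification, blending, juvenile
## response, the full cohort parameter vector, and rule-based mortality
## attribution.

#' Detect cohort windows from adult recruitment events
#'
#' A cohort window is a maximal run of adult recruitment events separated
#' from other runs by at least `min_gap` years: the per-site event
#' sequence is split at every inter-event gap `>= min_gap`. Pulses
#' typically last under `max_pulse` years; longer windows are kept but
#' flagged `extended`. Isolated single recruits form singleton windows.
#'
#' @param plants a `kelp_plants` table (recruit dates are used), or a data
#'   frame with `site_id` and `date` columns of recruitment events.
#' @param min_gap minimum separation between cohorts, years (default 1).
#' @param max_pulse advisory maximum pulse span, years (default 1.5).
#' @return a `kelp_windows` data frame: `site_id`, `cohort_number`
#'   (1-based per site in time order), `cohort_id`, `start`, `end`,
#'   `n_recruits`, `extended`.
#' @export
detect_cohort_windows <- function(plants, min_gap = 1, max_pulse = 1.5) {
  dates <- if ("recruit_date" %in% names(plants)) plants$recruit_date else plants$date
  df <- data.frame(site_id = plants$site_id, date = dates)
  out <- lapply(split(df, df$site_id), function(g) {
    t <- sort(g$date)
    if (length(t) == 0) return(NULL)
    brk <- which(diff(t) >= min_gap - 1e-9)
    seg <- rep(seq_len(length(brk) + 1), diff(c(0, brk, length(t))))
    starts <- tapply(t, seg, min); ends <- tapply(t, seg, max)
    data.frame(site_id = g$site_id[1], cohort_number = seq_along(starts),
               start = as.numeric(starts), end = as.numeric(ends),
               n_recruits = as.integer(table(seg)),
               extended = as.numeric(ends) - as.numeric(starts) > max_pulse + 1e-9)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(site_id = character(), cohort_number = integer(),
                      start = numeric(), end = numeric(),
                      n_recruits = integer(), extended = logical())
  out$cohort_id <- paste(out$site_id, out$cohort_number, sep = "-")
  rownames(out) <- NULL
  class(out) <- unique(c("kelp_windows", class(out)))
  out[, c("site_id", "cohort_number", "cohort_id", "start", "end",
          "n_recruits", "extended")]
}

#' Assign plants to cohort windows
#'
#' Each plant joins the window of its site whose `[start, end]` interval
#' contains its adult recruitment date. Windows constructed by
#' [detect_cohort_windows()] cover every recruit; any plant that
#' nevertheless falls outside all windows is left unassigned and reported
#' in the `"unassigned"` attribute.
#'
#' @param windows a `kelp_windows` table.
#' @param plants a `kelp_plants` table from the same sites.
#' @return `plants` with `cohort_id` filled in.
#' @export
assign_plants <- function(windows, plants) {
  for (site in unique(windows$site_id)) {
    w <- windows[windows$site_id == site, ]
    w <- w[order(w$start), ]
    if (nrow(w) > 1 && any(w$start[-1] <= w$end[-nrow(w)] + 1e-9))
      stopf("overlapping cohort windows at site '%s'", site)
  }
  idx <- rep(NA_character_, nrow(plants))
  for (i in seq_len(nrow(windows))) {
    hit <- plants$site_id == windows$site_id[i] &
      plants$recruit_date >= windows$start[i] - 1e-9 &
      plants$recruit_date <= windows$end[i] + 1e-9
    idx[hit] <- windows$cohort_id[i]
  }
  plants$cohort_id <- idx
  un <- plants$plant_id[is.na(idx) & plants$site_id %in% windows$site_id]
  if (length(un))
    warnf("%d plant(s) fell outside all cohort windows", length(un))
  attr(plants, "unassigned") <- un
  plants
}

#' Classify cohorts as pulsed or trickled
#'
#' A cohort is *pulsed* when at least 80% of its plants recruited to
#' adulthood within the first year after the appearance of the first
#' plant, and its recruitment is separated from neighbouring cohorts by at
#' least one year on both sides (series edges count as separated);
#' otherwise it is *trickled*.
#'
#' @param windows a `kelp_windows` table.
#' @param plants a `kelp_plants` table with `cohort_id` assigned.
#' @param first_year_frac pulse threshold on the first-year fraction
#'   (default 0.8, inclusive).
#' @param min_gap required separation from neighbouring windows (years).
#' @return `windows` with logical column `pulsed`.
#' @export
classify_pulse <- function(windows, plants, first_year_frac = 0.8, min_gap = 1) {
  windows$pulsed <- NA
  for (i in seq_len(nrow(windows))) {
    r <- plants[!is.na(plants$cohort_id) & plants$cohort_id == windows$cohort_id[i], ]
    if (nrow(r) == 0) next
    frac <- mean(r$recruit_date <= windows$start[i] + 1 + 1e-9)
    w <- windows[windows$site_id == windows$site_id[i], ]
    prev <- w[w$end < windows$start[i] - 1e-9, ]
    nxt <- w[w$start > windows$end[i] + 1e-9, ]
    gap_ok <- (nrow(prev) == 0 || windows$start[i] - max(prev$end) >= min_gap - 1e-9) &&
      (nrow(nxt) == 0 || min(nxt$start) - windows$end[i] >= min_gap - 1e-9)
    windows$pulsed[i] <- frac >= first_year_frac - 1e-9 && gap_ok
  }
  windows
}

#' Flag cohorts blended with survivors of previous cohorts
#'
#' A cohort is *blended* when at least one plant of any earlier cohort at
#' the site is still observed alive at the cohort's onset date, producing
#' a mixed-age stand.
#'
#' @inheritParams classify_pulse
#' @return `windows` with logical column `blended`.
#' @export
detect_blending <- function(windows, plants) {
  windows$blended <- NA
  for (i in seq_len(nrow(windows))) {
    onset <- windows$start[i]
    prev <- plants$site_id == windows$site_id[i] &
      plants$recruit_date < onset - 1e-9
    windows$blended[i] <- any(prev & plants$last_date >= onset - 1e-9)
  }
  windows
}

## Absolute death dates of a roster (NA for censored plants).
roster_death_dates <- function(roster, convention = "midpoint", step = 0.25) {
  ls <- lifespan(roster, convention, step)
  ifelse(ls$event, roster$recruit_date + ls$duration, NA_real_)
}

## Date at which cumulative mortality of a roster first reaches `frac`
## of its N; NA if never reached (living plants cannot die in-series).
dieoff_date <- function(roster, frac, convention = "midpoint") {
  deaths <- sort(roster_death_dates(roster, convention))
  need <- ceiling(frac * nrow(roster) - 1e-9)
  if (length(deaths) < need || need == 0) return(NA_real_)
  deaths[need]
}

## Site-level census sums of one count column -> data.frame(date, value).
site_census_sum <- function(census, site, col) {
  g <- census[census$site_id == site, ]
  agg <- tapply(g[[col]], g$date, sum)
  data.frame(date = as.numeric(names(agg)), value = as.numeric(agg))
}

#' Juvenile recruitment response after a cohort die-off
#'
#' For each cohort with a predecessor, tests whether juvenile giant kelp
#' recruitment appeared within `lag` years (one quarterly census) of the
#' date at which at least `dieoff_fraction` of the preceding cohort's
#' plants had died: the site juvenile count must rise above its level at
#' the last census before the die-off date. `NA` when the predecessor
#' never reaches the die-off fraction before the cohort's onset.
#'
#' @inheritParams classify_pulse
#' @param census a validated census table.
#' @param dieoff_fraction cumulative-mortality threshold (default 0.95).
#' @param lag response window in years (default 0.25, i.e. 3 months).
#' @param convention death-time convention ([lifespan()]).
#' @return `windows` with logical column `juvenile_response` (`NA` where
#'   not applicable).
#' @export
juvenile_response <- function(windows, plants, census, dieoff_fraction = 0.95,
                              lag = 0.25, convention = "midpoint") {
  windows$juvenile_response <- NA
  for (i in seq_len(nrow(windows))) {
    if (windows$cohort_number[i] == 1) next
    prev_id <- paste(windows$site_id[i], windows$cohort_number[i] - 1, sep = "-")
    roster <- plants[!is.na(plants$cohort_id) & plants$cohort_id == prev_id, ]
    if (nrow(roster) == 0) next
    t95 <- dieoff_date(roster, dieoff_fraction, convention)
    if (is.na(t95) || t95 > windows$start[i] + 1e-9) next
    # baseline precedes the die-off itself (taken before half the cohort died)
    t50 <- dieoff_date(roster, 0.5, convention)
    if (is.na(t50)) t50 <- t95
    juv <- site_census_sum(census, windows$site_id[i], "macro_juvenile")
    before <- juv$value[juv$date < t50 - 1e-9]
    baseline <- if (length(before)) before[length(before)] else 0
    after <- juv$value[juv$date > t95 + 1e-9 & juv$date <= t95 + lag + 1e-9]
    windows$juvenile_response[i] <- length(after) > 0 && any(after > baseline)
  }
  windows
}

#' Rule-based mortality attribution
#'
#' An explicit, rule-based approximation of a field-note judgement. The
#' cohort's terminal phase is the interval over which cumulative mortality
#' rises from 50% to 95%. Causes fire on covariates over that phase:
#' *heat* when the 80th percentile of bottom temperature exceeds
#' `heat_threshold`; *waves* when any weekly wave energy exceeds
#' `wave_threshold` (J m^-2); *sea urchins* when mean purple urchin
#' density exceeds `psu_threshold` or mean red urchin density exceeds
#' `rsu_threshold` (individuals m^-2). Cohorts smaller than `min_n` are
#' labelled "small cohort"; multiple fired causes combine ("heat/waves");
#' no fired cause gives "not known". Amphipod infestation is a field call
#' and is never auto-assigned.
#'
#' @param roster the cohort's plants (a `kelp_plants` subset).
#' @param temperature temperature series (`date`, `temperature`).
#' @param waves weekly wave-energy series (`date`, `energy`),
#'   from [wave_energy_series()].
#' @param census a validated census table (urchin densities).
#' @param site_id the cohort's site.
#' @param heat_threshold,wave_threshold,psu_threshold,rsu_threshold rule
#'   thresholds (defaults 16 degC, 6800 J m^-2, 2.5 m^-2, 0.25 m^-2).
#' @param min_n small-cohort threshold (default 5 plants).
#' @param convention death-time convention.
#' @return a single label string.
#' @export
attribute_mortality <- function(roster, temperature, waves, census, site_id,
                                heat_threshold = 16, wave_threshold = 6800,
                                psu_threshold = 2.5, rsu_threshold = 0.25,
                                min_n = 5, convention = "midpoint") {
  if (nrow(roster) < min_n) return("small cohort")
  t50 <- dieoff_date(roster, 0.50, convention)
  t95 <- dieoff_date(roster, 0.95, convention)
  if (is.na(t50) || is.na(t95)) return("not known")
  phase <- c(t50, max(t95, t50 + 0.25))
  causes <- character()
  temp_in <- temperature$temperature[temperature$date >= phase[1] &
                                     temperature$date < phase[2]]
  temp_in <- temp_in[!is.na(temp_in)]
  if (length(temp_in) && stats::quantile(temp_in, 0.8, type = 7) > heat_threshold)
    causes <- c(causes, "heat")
  wave_in <- waves$energy[waves$date >= phase[1] & waves$date < phase[2]]
  if (length(wave_in) && any(wave_in > wave_threshold, na.rm = TRUE))
    causes <- c(causes, "waves")
  cen <- census[census$site_id == site_id & census$date >= phase[1] &
                census$date < phase[2] + 1e-9, ]
  if (nrow(cen) && (mean(cen$psu_density) > psu_threshold ||
                    mean(cen$rsu_density) > rsu_threshold))
    causes <- c(causes, "urchins")
  if (!length(causes)) return("not known")
  if (identical(causes, "urchins")) return("sea urchins")
  paste(causes, collapse = "/")
}

#' Cohort parameter vector
#'
#' Assembles one row per detected cohort: roster-derived demography (N,
#' singles, mean lifespan, mean per-plant maximum stipe count,
#' Kaplan-Meier survival quantiles at p = 0.25/0.5/0.75/0.95),
#' pre-recruitment context from the census over the year before onset
#' (peak juvenile and pre-adult counts, distinct prior adults alive in
#' that year as potential spore provisioning, mean pooled scaled
#' understory guilds and raw turf cover), covariates over the cohort's
#' lifetime window `[onset, onset + t95]` where `t95` is the 95th
#' Kaplan-Meier survival quantile (falling back to the longest observed
#' lifespan under heavy censoring): 80th percentile of bottom temperature
#' and of weekly wave energy, mean urchin densities; plus the
#' pulsed/trickled, blended and juvenile-response flags, rule-based
#' mortality cause, site depth and calendar decade of onset.
#'
#' @param windows a `kelp_windows` table.
#' @param plants a `kelp_plants` table with `cohort_id` assigned
#'   ([assign_plants()]).
#' @param census a validated census table.
#' @param temperature temperature series (`date`, `temperature`),
#'   gap-filled ([interpolate_gaps()]).
#' @param waves weekly wave-energy series ([wave_energy_series()]).
#' @param site_meta optional site metadata ([load_site_meta()]).
#' @param convention death-time convention ([lifespan()]).
#' @param cov_quantile covariate quantile level (default 0.8).
#' @param context_window `"preceding"` (default; the year before onset),
#'   `"centred"`, or `"following"` — placement of the one-year context
#'   window for juveniles, pre-adults, prior adults and understory.
#' @param mortality_config named list overriding [attribute_mortality()]
#'   thresholds.
#' @return a `kelp_cohorts` data frame, one row per cohort.
#' @export
cohort_parameters <- function(windows, plants, census, temperature, waves,
                              site_meta = NULL, convention = "midpoint",
                              cov_quantile = 0.8,
                              context_window = c("preceding", "centred", "following"),
                              mortality_config = list()) {
  context_window <- match.arg(context_window)
  if (is.na(match("pulsed", names(windows))))
    windows <- classify_pulse(windows, plants)
  if (is.na(match("blended", names(windows))))
    windows <- detect_blending(windows, plants)
  if (is.na(match("juvenile_response", names(windows))))
    windows <- juvenile_response(windows, plants, census, convention = convention)

  guilds <- scale_features(pool_guilds(census))
  under_cols <- c("stipitate", "laminate", "brown_turf", "red_turf",
                  "articulated_coralline", "desmarestia")
  guild_under <- rowSums(as.matrix(guilds[, under_cols]))
  cover_under <- census$brown_turf + census$red_turf +
    census$articulated_coralline + census$cystoseira

  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    site <- windows$site_id[i]
    onset <- windows$start[i]
    roster <- plants[!is.na(plants$cohort_id) &
                     plants$cohort_id == windows$cohort_id[i], ]
    if (nrow(roster) == 0) next
    ls <- lifespan(roster, convention)
    km <- km_fit(ls$duration, ls$event)
    kmq <- km_quantile(km, c(0.25, 0.5, 0.75, 0.95))
    t95 <- if (is.na(kmq[4])) max(ls$duration) else kmq[4]
    t95 <- max(t95, 0.25)

    ctx <- switch(context_window,
                  preceding = c(onset - 1, onset),
                  centred = c(onset - 0.5, onset + 0.5),
                  following = c(onset, onset + 1))
    cen_site <- census$site_id == site
    in_ctx <- cen_site & census$date >= ctx[1] - 1e-9 & census$date <= ctx[2] + 1e-9
    peak <- function(col) {
      if (!any(in_ctx)) return(0)
      max(tapply(census[[col]][in_ctx], census$date[in_ctx], sum))
    }
    ad <- sum(plants$site_id == site & plants$recruit_date < onset - 1e-9 &
              plants$last_date >= ctx[1] - 1e-9)

    cov_int <- c(onset, onset + t95)
    env_end <- min(max(temperature$date, na.rm = TRUE),
                   max(waves$date, na.rm = TRUE))
    env_start <- max(min(temperature$date, na.rm = TRUE),
                     min(waves$date, na.rm = TRUE))
    if (env_start > onset + 0.3 || env_end < cov_int[2] - 0.3)
      stopf("environment series do not cover [%.2f, %.2f] for cohort %s",
            onset, cov_int[2], windows$cohort_id[i])
    # cohorts recruiting at the series end: use the last quarter available
    if (cov_int[2] > env_end) cov_int <- c(min(cov_int[1], env_end - 0.25), env_end)
    temp80 <- window_quantile(temperature, cov_int, cov_quantile)
    wave80 <- window_quantile(waves, cov_int, cov_quantile)
    in_cov <- cen_site & census$date >= cov_int[1] - 1e-9 &
      census$date <= cov_int[2] + 1e-9
    psu <- if (any(in_cov)) mean(census$psu_density[in_cov]) else NA_real_
    rsu <- if (any(in_cov)) mean(census$rsu_density[in_cov]) else NA_real_

    nobs <- vapply(roster$stipe_series, function(ss)
      if (is.null(ss)) NA_integer_ else nrow(ss), 0L)
    stmax <- vapply(roster$stipe_series, function(ss)
      if (is.null(ss) || nrow(ss) == 0) NA_real_ else max(ss$stipes), 0)
    singles <- if (anyNA(nobs)) sum(roster$last_date == roster$recruit_date)
               else sum(nobs == 1)

    margs <- c(list(roster = roster, temperature = temperature, waves = waves,
                    census = census, site_id = site, convention = convention),
               mortality_config)
    rows[[i]] <- data.frame(
      site_id = site, cohort_number = windows$cohort_number[i],
      cohort_id = windows$cohort_id[i], onset_date = onset,
      window_end = windows$end[i],
      N = nrow(roster), singles = singles,
      PA = peak("macro_preadult"), juveniles_1yr = peak("macro_juvenile"),
      Ad = ad,
      understory_1yr = if (any(in_ctx)) mean(guild_under[in_ctx]) else NA_real_,
      understory_cover_1yr = if (any(in_ctx)) mean(cover_under[in_ctx]) else NA_real_,
      life_mn = mean(ls$duration), st_max_mn = mean(stmax),
      km_q25 = kmq[1], km_q50 = kmq[2], km_q75 = kmq[3], km_q95 = kmq[4],
      t95 = t95,
      pulsed = windows$pulsed[i], blended = windows$blended[i],
      juvenile_response = windows$juvenile_response[i],
      alive = any(!roster$dead),
      depth = if (!is.null(site_meta))
        site_meta$depth[match(site, site_meta$site_id)] else NA_real_,
      decade = sprintf("%ds", 10 * (floor(onset) %/% 10)),
      psu_density = psu, rsu_density = rsu,
      temp80 = temp80, wave80 = wave80,
      mortality_cause = do.call(attribute_mortality, margs))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- unique(c("kelp_cohorts", class(out)))
  out
}

#' @export
print.kelp_cohorts <- function(x, ...) {
  cat(sprintf("Cohort table: %d cohorts at %d site(s), %d plants total\n",
              nrow(x), length(unique(x$site_id)), sum(x$N)))
  cat(sprintf("  pulsed %.2f | blended %.2f | still alive %d\n",
              mean(x$pulsed), mean(x$blended), sum(x$alive)))
  invisible(x)
}

#' Demographic event summary
#'
#' Proportions of trickled/pulsed cohort appearance, blending with
#' previous cohorts, juvenile recruitment within three months of the
#' previous cohort's die-off, and the distribution of rule-based mortality
#' causes — the pipeline's tabular summary of cohort demographic events.
#'
#' @param cohorts a `kelp_cohorts` table.
#' @return data frame `event`, `category`, `proportion`.
#' @export
demographic_summary <- function(cohorts) {
  jr <- cohorts$juvenile_response[!is.na(cohorts$juvenile_response)]
  mc <- sort(table(cohorts$mortality_cause[!cohorts$alive]), decreasing = TRUE)
  rows <- rbind(
    data.frame(event = "Cohort appearance", category = c("Trickled", "Pulsed"),
               proportion = c(mean(!cohorts$pulsed), mean(cohorts$pulsed))),
    data.frame(event = "Juvenile recruitment",
               category = c("Blended with previous cohort(s)",
                            "Within 3 months after previous cohort"),
               proportion = c(mean(cohorts$blended),
                              if (length(jr)) mean(jr) else NA_real_)),
    if (length(mc)) data.frame(event = "Mortality cause (rule-based)",
                               category = names(mc),
                               proportion = as.numeric(mc) / sum(mc)))
  rownames(rows) <- NULL
  rows
}
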