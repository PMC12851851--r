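## Individual-based simulator of disturbance-driven kelp forest dynamics.
## Emits census, plant, and environment tables in the package's data model
## together with the generating ground truth (recruitment episodes and
## memberships, pulsed/trickled labels, hazard coefficients), so every
## pipeline stage can be tested against known structure.

#' Simulation configuration
#'
#' Builds the nested configuration list for [simulate_dataset()]. The
#' defaults emulate the San Diego study design: 20 sites at 8-21 m
#' established between 1983 and 2007, four transects of ten 5 x 2 m
#' quadrats each, quarterly censuses through 2023, El Nino / marine heat
#' wave and storm disturbances on their historical years, pulsed
#' post-disturbance recruitment with understory encroachment that
#' accelerates after the 2014-2015 marine heat wave, and adult mortality
#' hazards driven by temperature anomaly, storm wave energy, and sea
#' urchin density.
#'
#' @param n_sites number of sites (default 20).
#' @param years simulated span `c(first, last)` in calendar years.
#' @param seed mandatory master seed.
#' @param ... named overrides of any top-level config block
#'   (`forcing`, `disturbances`, `recruitment`, `mortality`,
#'   `understory`, `urchins`, `stipes`, `depths`, `established`,
#'   `n_transects`, `n_quadrats`); sub-lists are merged over the defaults.
#' @return a `kelp_sim_config` list.
#' @export
simulation_config <- function(n_sites = 20, years = c(1983, 2023), seed = 1, ...) {
  if (is.null(seed)) stopf("a seed is mandatory")
  # depth / establishment-year pools mirroring the long-term monitoring design
  depth_pool <- c(18, 12, 15, 18, 18, 15, 15, 18, 21, 8, 16, 17, 16, 12,
                  15, 18, 12, 15, 18, 12)
  est_pool <- c(1983, 1983, 1983, 1983, 1983, 1992, 1992, 1995, 1995, 1997,
                1997, 2006, 2006, 2004, 2004, 2004, 2004, 1996, 2007, 1997)
  cfg <- list(
    n_sites = n_sites, years = years, cadence = 0.25,
    n_transects = 4, n_quadrats = 10, seed = seed,
    depths = rep_len(depth_pool, n_sites),
    established = pmax(years[1], pmin(rep_len(est_pool, n_sites), years[2] - 5)),
    forcing = list(cadence = 1 / 2922, temp_mean = 14.2, temp_amp = 2.1,
                   temp_phase = 0.70, ar_tau = 0.03, ar_sd = 0.45,
                   hs_shape = 2.0, hs_scale = 0.75, winter_amp = 0.45),
    disturbances = data.frame(
      year = c(1983.0, 1988.0, 1992.0, 1997.5, 2014.5, 2016.0, 2021.0, 2023.0),
      duration = c(1.0, 0.25, 0.25, 1.0, 1.75, 0.50, 0.25, 0.25),
      heat_anom = c(2.6, 0, 0, 2.8, 3.0, 1.5, 0, 0),
      wave_hs = c(4.2, 5.0, 4.0, 0, 0, 4.2, 4.0, 4.2)),
    recruitment = list(mode = "mechanistic", juv_rate = 55, p_jp = 0.45,
                       p_pa = 0.55, light_threshold = 0.6,
                       understory_threshold = 0.6, warm_limit = 2.0,
                       secular_decline = 0.7, trickle_frac = 0.10,
                       trickle_gate = 0.35, bank_quarters = 4,
                       schedule = NULL, pulse_size = 60, pulse_span = 0.75),
    mortality = list(baseline = 0.40, first_year = 0.35, beta_temp = 0.40,
                     beta_wave = 1.6, wave_threshold = 6800,
                     beta_urchin = 0.30),
    understory = list(init = 0.15, rate = 0.45, rate_post_shift = 0.8,
                      shift_year = 2015, decay = 0.03, wave_scour = 0.5,
                      scour_post_mult = 0.35),
    urchins = list(psu_mean = 0.5, rsu_mean = 0.05, ar_phi = 0.85,
                   ar_sd = 0.5, outbreak_prob = 0.01, outbreak_mult = 7,
                   outbreak_sites = 0.15),
    stipes = list(target_meanlog = log(19), target_sdlog = 0.45,
                  peak_age = 1.6, secular_decline = 0.45))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) && !is.data.frame(dots[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  if (cfg$cadence <= 0 || abs(1 / cfg$cadence - round(1 / cfg$cadence)) > 1e-9)
    stopf("census cadence must divide one year")
  structure(cfg, class = c("kelp_sim_config", "list"))
}

## Smooth 0->1->0 event profile over [year, year + duration].
event_profile <- function(t, year, duration) {
  u <- (t - year) / duration
  ifelse(u >= 0 & u <= 1, sin(pi * u)^2, 0)
}

#' Simulate environmental forcing
#'
#' Bottom temperature = seasonal sinusoid + AR(1) noise + scheduled warm
#' anomalies; significant wave height = seasonally modulated Weibull draws
#' + scheduled storm spikes, with a coincident period. Deterministic given
#' the seed.
#'
#' @param config a [simulation_config()] list.
#' @param seed RNG seed (default: the config seed).
#' @return list with `temperature` (`date`, `temperature`) and `waves`
#'   (`date`, `hs`, `period`) data frames at the configured cadence.
#' @export
simulate_forcing <- function(config, seed = config$seed) {
  fc <- config$forcing
  t <- seq(config$years[1], config$years[2] + 1e-9, by = fc$cadence)
  frac <- t %% 1
  with_seed(child_seed(seed, 1), {
    seasonal <- fc$temp_mean + fc$temp_amp * cos(2 * pi * (frac - fc$temp_phase))
    phi <- exp(-fc$cadence / fc$ar_tau)
    innov_sd <- fc$ar_sd * sqrt(1 - phi^2)
    noise <- as.numeric(stats::filter(stats::rnorm(length(t), 0, innov_sd),
                                      phi, method = "recursive"))
    temp <- seasonal + noise
    for (i in seq_len(nrow(config$disturbances))) {
      d <- config$disturbances[i, ]
      if (d$heat_anom > 0)
        temp <- temp + d$heat_anom * event_profile(t, d$year, d$duration)
    }
    winter <- 1 + fc$winter_amp * cos(2 * pi * (frac - 0.02))
    hs <- fc$hs_scale * winter * stats::rweibull(length(t), fc$hs_shape)
    for (i in seq_len(nrow(config$disturbances))) {
      d <- config$disturbances[i, ]
      if (d$wave_hs > 0) {
        prof <- event_profile(t, d$year, max(d$duration, 0.1))
        hs <- pmax(hs, d$wave_hs * prof * (0.85 + 0.3 * stats::runif(length(t))))
      }
    }
    period <- pmin(18, pmax(6, 8 + 1.6 * hs + stats::rnorm(length(t), 0, 0.8)))
    list(temperature = data.frame(date = t, temperature = temp),
         waves = data.frame(date = t, hs = hs, period = period))
  })
}

## Quarterly summaries of forcing for the plant dynamics: per quarter end
## date, the mean temperature anomaly and the max weekly wave energy in
## the preceding quarter.
quarter_forcing <- function(forcing, qdates, cadence = 0.25) {
  anom <- seasonal_detrend(forcing$temperature)
  wk <- wave_energy_series(forcing$waves)
  idx_a <- findInterval(anom$date, qdates - cadence + 1e-9)
  idx_w <- findInterval(wk$date, qdates - cadence + 1e-9)
  a <- tapply(anom$anomaly, factor(idx_a, levels = seq_along(qdates)),
              mean, na.rm = TRUE)
  e <- tapply(wk$energy, factor(idx_w, levels = seq_along(qdates)),
              max, na.rm = TRUE)
  a[!is.finite(a)] <- 0; e[!is.finite(e)] <- 0
  data.frame(date = qdates, anom = as.numeric(a), energy = as.numeric(e))
}

#' Simulate one site
#'
#' Quarterly individual-based dynamics on the site's 4 x 10 quadrat grid:
#' juveniles recruit when the adult canopy is open and understory cover is
#' below the competition threshold, mature through the pre-adult stage to
#' adulthood with fixed one-quarter lags; adult mortality hazard is
#' `baseline * exp(beta_T * anomaly + beta_W * 1[energy > threshold] +
#' beta_U * urchins)` with an extra first-year component (self-thinning);
#' understory encroaches logistically when the canopy is low and is
#' scoured by storms; per-plant stipe counts rise to an individual target
#' and decline with age. Adult recruitment episodes separated by at least
#' a year of recruitment silence define the ground-truth cohorts. A
#' `"scheduled"` recruitment mode instead plants adult recruitment pulses
#' at configured times (exact planted truth; every pulse yields at least
#' one recruit).
#'
#' @param config a [simulation_config()] list.
#' @param forcing output of [simulate_forcing()].
#' @param site_id site identifier.
#' @param depth site depth (m).
#' @param established first census year.
#' @param seed RNG seed for this site.
#' @param qforce optional precomputed [quarter_forcing()] table.
#' @return list with `census`, `plants`, and `truth` (episode windows,
#'   memberships, realized pulsed labels).
#' @export
simulate_site <- function(config, forcing, site_id, depth, established,
                          seed, qforce = NULL) {
  qdates <- seq(max(established, config$years[1]), config$years[2] + 1e-9,
                by = config$cadence)
  if (is.null(qforce)) qforce <- quarter_forcing(forcing, qdates, config$cadence)
  qf <- qforce[match(round(qdates * 4), round(qforce$date * 4)), ]
  nq <- config$n_transects * config$n_quadrats
  quad_tr <- rep(seq_len(config$n_transects), each = config$n_quadrats)
  quad_id <- rep(seq_len(config$n_quadrats), config$n_transects)
  mo <- config$mortality; rc <- config$recruitment
  un <- config$understory; st <- config$stipes; ur <- config$urchins

  # depth modulation: deeper sites are cooler, see less orbital wave energy,
  # and are darker (lower canopy threshold under which recruitment proceeds)
  heat_scale <- max(0.4, 1 - 0.045 * (depth - 12))
  wave_scale <- (15 / depth)^1.5
  light_thr <- rc$light_threshold * (15 / depth)^0.8

  with_seed(child_seed(seed, 17), {
    # site-level urchin series (AR(1) on log scale, rare outbreaks)
    nt <- length(qdates)
    lp <- as.numeric(stats::filter(stats::rnorm(nt, 0, ur$ar_sd * sqrt(1 - ur$ar_phi^2)),
                                   ur$ar_phi, method = "recursive"))
    outbreak_site <- stats::runif(1) < ur$outbreak_sites
    ob <- rep(1, nt)
    if (outbreak_site) {
      state <- FALSE
      for (i in seq_len(nt)) {
        if (!state && stats::runif(1) < ur$outbreak_prob) state <- TRUE
        else if (state && stats::runif(1) < 0.15) state <- FALSE
        if (state) ob[i] <- ur$outbreak_mult
      }
    }
    psu_t <- ur$psu_mean * exp(lp) * ob
    rsu_t <- ur$rsu_mean * exp(0.8 * lp) * ifelse(ob > 1, 3, 1)

    # plant state (columns grow as plants recruit)
    max_plants <- 20000L
    p_quad <- integer(0); p_recruit <- numeric(0); p_target <- numeric(0)
    p_alive <- logical(0); p_last <- numeric(0); p_episode <- integer(0)
    obs_plant <- integer(0); obs_date <- numeric(0); obs_stipes <- integer(0)
    juv <- rep(0L, nq); pre <- rep(0L, nq)
    u_cov <- rep(un$init, nq)
    des_level <- 0
    episode <- 0L; last_recruit <- -Inf
    recr_bank <- 0L; prev_closed <- TRUE; a_recent <- 1
    census_rows <- vector("list", nt)
    span <- diff(config$years)

    draw_target <- function(n, date) {
      dec <- 1 - st$secular_decline * (date - config$years[1]) / span
      pmax(6, stats::rlnorm(n, st$target_meanlog + log(max(dec, 0.3)), st$target_sdlog))
    }
    spawn <- function(n, quads, date) {
      if (n == 0) return(invisible())
      if (date - last_recruit >= 1 - 1e-9) episode <<- episode + 1L
      last_recruit <<- date
      p_quad <<- c(p_quad, quads)
      p_recruit <<- c(p_recruit, rep(date, n))
      p_target <<- c(p_target, draw_target(n, date))
      p_alive <<- c(p_alive, rep(TRUE, n))
      p_last <<- c(p_last, rep(date, n))
      p_episode <<- c(p_episode, rep(episode, n))
    }

    # initial stand at site establishment (mechanistic mode only; scheduled
    # runs start bare so the planted pulses are the only recruitment truth)
    if (rc$mode == "mechanistic") {
      n0 <- stats::rpois(nq, 1.1)
      spawn(sum(n0), rep(seq_len(nq), n0), qdates[1])
    }

    for (i in seq_along(qdates)) {
      date <- qdates[i]
      anom <- qf$anom[i] * heat_scale
      energy <- qf$energy[i] * wave_scale
      storm <- energy > mo$wave_threshold

      # maturation: pre-adults -> adults, juveniles -> pre-adults
      if (rc$mode == "mechanistic") {
        new_ad <- stats::rbinom(nq, pre, rc$p_pa)
        spawn(sum(new_ad), rep(seq_len(nq), new_ad), date)
        pre <- stats::rbinom(nq, juv, rc$p_jp)
        juv <- rep(0L, nq)
        # juvenile recruitment under open canopy, low understory, cool water
        alive_idx <- which(p_alive)
        a_mean <- length(alive_idx) / nq
        openness <- max(0, 1 - a_mean / light_thr)
        # canopy-loss events open a short gametophyte-bank recruitment pulse
        # (spores provisioned by the recently standing canopy); outside it a
        # low background trickle persists where understory is prevalent
        closed_now <- a_mean >= light_thr
        if (prev_closed && !closed_now) recr_bank <- rc$bank_quarters
        prev_closed <- closed_now
        a_recent <- max(a_recent * 0.8, a_mean)  # decaying memory of canopy
        if (openness > 0 && anom < rc$warm_limit) {
          seasonal <- if ((date %% 1) < 0.3) 1 else 0.4  # winter/spring window
          spore <- min(1, 0.3 + a_recent / 1.0)
          secular <- 1 - rc$secular_decline * (date - config$years[1]) / span
          lam_pulse <- if (recr_bank > 0)
            rc$juv_rate / 4 * pmax(0, 1 - u_cov / rc$understory_threshold) else 0
          lam_trickle <- rc$juv_rate / 4 * rc$trickle_frac *
            (u_cov >= rc$trickle_gate)
          lam <- (lam_pulse + lam_trickle) * seasonal * openness * spore * secular
          juv <- juv + stats::rpois(nq, lam)
        }
        if (recr_bank > 0) recr_bank <- recr_bank - 1L
      } else {
        # scheduled pulses: plant adult recruits directly
        for (ps in seq_along(rc$schedule)) {
          p0 <- rc$schedule[ps]
          if (date >= p0 - 1e-9 && date <= p0 + rc$pulse_span + 1e-9) {
            nsteps <- floor(rc$pulse_span / config$cadence) + 1
            n_new <- stats::rpois(1, rc$pulse_size / nsteps)
            if (abs(date - p0) < 1e-9) n_new <- max(1L, n_new)
            spawn(n_new, sample.int(nq, n_new, replace = TRUE), date)
          }
        }
        juv <- stats::rpois(nq, ifelse(any(abs(rc$schedule - date - 0.5) < 0.26), 3, 0.2))
        pre <- stats::rbinom(nq, juv, rc$p_jp)
      }

      # census snapshot
      alive_idx <- which(p_alive)
      age <- date - p_recruit[alive_idx]
      shape <- (pmax(age, 0.125) / st$peak_age) * exp(1 - pmax(age, 0.125) / st$peak_age)
      stipes <- pmax(ifelse(age < 0.75, 4, 1),
                     round(p_target[alive_idx] * shape +
                             stats::rnorm(length(alive_idx), 0, 0.8)))
      obs_plant <- c(obs_plant, alive_idx)
      obs_date <- c(obs_date, rep(date, length(alive_idx)))
      obs_stipes <- c(obs_stipes, stipes)
      p_last[alive_idx] <- date

      ad_per_quad <- tabulate(p_quad[alive_idx], nq)
      st_per_quad <- if (length(alive_idx))
        as.numeric(tapply(stipes, factor(p_quad[alive_idx], levels = seq_len(nq)),
                          sum)) else rep(0, nq)
      st_per_quad[is.na(st_per_quad)] <- 0
      des_level <- max(des_level * 0.45, if (storm || anom > 2) 6 else 0)
      census_rows[[i]] <- data.frame(
        site_id = site_id, transect_id = quad_tr, quadrat_id = quad_id,
        date = date,
        macro_adult = ad_per_quad, macro_preadult = pre, macro_juvenile = juv,
        stipe_count = as.integer(st_per_quad),
        stipitate = stats::rpois(nq, 4 * u_cov),
        laminate = stats::rpois(nq, 3 * u_cov),
        desmarestia = stats::rpois(nq, des_level * pmax(0, 1 - u_cov)),
        brown_turf = pmin(1, pmax(0, 0.50 * u_cov + stats::rnorm(nq, 0, 0.02))),
        red_turf = pmin(1, pmax(0, 0.28 * u_cov + stats::rnorm(nq, 0, 0.02))),
        articulated_coralline = pmin(1, pmax(0, 0.18 * u_cov + stats::rnorm(nq, 0, 0.01))),
        cystoseira = pmin(1, pmax(0, 0.12 * u_cov + stats::rnorm(nq, 0, 0.01))),
        psu_density = pmax(0, psu_t[i] * exp(stats::rnorm(nq, 0, 0.2))),
        rsu_density = pmax(0, rsu_t[i] * exp(stats::rnorm(nq, 0, 0.2))))

      if (i == length(qdates)) break

      # mortality over (date, date + cadence)
      if (length(alive_idx)) {
        lam <- (mo$baseline + mo$first_year * (age < 1)) *
          exp(mo$beta_temp * anom + mo$beta_wave * storm +
                mo$beta_urchin * psu_t[i])
        p_die <- 1 - exp(-lam * config$cadence)
        dies <- stats::runif(length(alive_idx)) < p_die
        p_alive[alive_idx[dies]] <- FALSE
        # abrupt mass mortality re-opens the recruitment window at once
        if (length(alive_idx) >= 10 && mean(dies) > 0.5)
          recr_bank <- max(recr_bank, rc$bank_quarters)
      }

      # understory: logistic encroachment when canopy open; storm scour
      rate <- if (date >= un$shift_year) un$rate_post_shift else un$rate
      canopy <- pmin(1, ad_per_quad / light_thr)
      u_cov <- u_cov + config$cadence *
        (rate * pmax(u_cov, 0.02) * (1 - u_cov) * (1 - canopy) - un$decay * u_cov)
      if (storm) {
        scour <- un$wave_scour *
          if (date >= un$shift_year) un$scour_post_mult else 1
        u_cov <- u_cov * (1 - scour)
      }
      u_cov <- pmin(0.98, pmax(0.01, u_cov))
    }

    census <- do.call(rbind, census_rows)
    n_plants <- length(p_quad)
    plant_ids <- sprintf("%s-p%05d", site_id, seq_len(n_plants))
    ss <- split(data.frame(date = obs_date, stipes = obs_stipes), obs_plant)
    series <- rep(list(data.frame(date = numeric(), stipes = numeric())), n_plants)
    series[as.integer(names(ss))] <- lapply(ss, function(d) d[order(d$date), ])
    plants <- plant_table(plant_ids, site_id, sprintf("%d-%d",
                          quad_tr[p_quad], quad_id[p_quad]),
                          p_recruit, p_last, !p_alive, series)
    truth_windows <- do.call(rbind, lapply(split(seq_len(n_plants), p_episode),
      function(ix) data.frame(site_id = site_id, episode = p_episode[ix[1]],
                              start = min(p_recruit[ix]), end = max(p_recruit[ix]),
                              n = length(ix))))
    truth_windows$pulsed <- vapply(seq_len(nrow(truth_windows)), function(j) {
      ix <- which(p_episode == truth_windows$episode[j])
      mean(p_recruit[ix] <= truth_windows$start[j] + 1 + 1e-9) >= 0.8
    }, TRUE)
    list(census = validate_census(census), plants = plants,
         truth = list(windows = truth_windows,
                      membership = data.frame(plant_id = plant_ids,
                                              episode = p_episode)))
  })
}

#' Simulate a full multi-site dataset
#'
#' Shared environmental forcing drives all sites; each site runs the
#' individual-based dynamics of [simulate_site()] with its own seed
#' stream. All emitted tables pass the core validators by construction.
#'
#' @param config a [simulation_config()] list.
#' @return list: `census`, `plants`, `temperature`, `waves`, `site_meta`,
#'   `truth` (per-site windows/memberships plus the hazard coefficients
#'   used), `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  forcing <- simulate_forcing(config)
  all_q <- seq(config$years[1], config$years[2] + 1e-9, by = config$cadence)
  qforce <- quarter_forcing(forcing, all_q, config$cadence)
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  res <- lapply(seq_len(config$n_sites), function(i)
    simulate_site(config, forcing, sites[i], config$depths[i],
                  config$established[i], seed = child_seed(config$seed, 1000 + i),
                  qforce = qforce))
  census <- validate_census(do.call(rbind, lapply(res, function(r)
    as.data.frame(r$census))))
  plants <- do.call(rbind, lapply(res, function(r) as.data.frame(r$plants)))
  plants <- validate_plants(plants)
  truth <- list(
    windows = do.call(rbind, lapply(res, function(r) r$truth$windows)),
    membership = do.call(rbind, lapply(res, function(r) r$truth$membership)),
    mortality = config$mortality)
  site_meta <- data.frame(site_id = sites, depth = config$depths,
                          year_established = config$established,
                          physiography = "simulated low-relief reef")
  list(census = census, plants = plants, temperature = forcing$temperature,
       waves = forcing$waves, site_meta = site_meta, truth = truth,
       config = config)
}

#' Canned deterministic fixtures
#'
#' Tiny hand-constructed datasets with known cohort structure, built by
#' explicit arithmetic (no random draws), for worked examples and
#' end-to-end tests.
#'
#' `"two_pulses"`: one site, 10 years, exactly two cohorts — the first
#' pulsed (20 plants, all recruited within half a year), the second
#' trickled (10 plants spread over 1.5 years). `"censored_tail"`: the
#' same site with five additional plants alive at the final census
#' (right-censored).
#'
#' @param name fixture name.
#' @return list with `census`, `plants`, `temperature`, `waves`,
#'   `site_meta`, `truth`.
#' @export
make_fixture <- function(name = c("two_pulses", "censored_tail")) {
  known <- c("two_pulses", "censored_tail")
  if (!name %in% known)
    stopf("unknown fixture '%s'; available: %s", name, paste(known, collapse = ", "))
  site <- "FIX1"
  qdates <- seq(2000, 2009.75, by = 0.25)
  # cohort 1: pulsed — 20 plants recruit 2000.00-2000.50, die through 2003
  r1 <- rep(c(2000.0, 2000.25, 2000.5), c(10, 6, 4))
  d1 <- 2000.75 + (seq_along(r1) %% 9) * 0.25       # last seen 2000.75..2002.75
  # cohort 2: trickled — 10 plants recruit 2005.00-2006.50 (60% in 1st yr)
  r2 <- c(rep(2005.0, 4), rep(2005.5, 2), rep(2006.25, 2), rep(2006.5, 2))
  d2 <- pmax(r2, 2006.5 + (seq_along(r2) %% 6) * 0.25)
  recruit <- c(r1, r2); last <- c(d1, d2)
  dead <- rep(TRUE, length(recruit))
  if (name == "censored_tail") {
    recruit <- c(recruit, rep(2008.0, 5))
    last <- c(last, rep(2009.75, 5))
    dead <- c(dead, rep(FALSE, 5))
  }
  n <- length(recruit)
  ids <- sprintf("%s-p%03d", site, seq_len(n))
  series <- lapply(seq_len(n), function(i) {
    dts <- seq(recruit[i], last[i], by = 0.25)
    k <- seq_along(dts)
    data.frame(date = dts, stipes = pmax(4, 4 + 2 * pmin(k - 1, 4) - (k > 8)))
  })
  plants <- plant_table(ids, site, "1-1", recruit, last, dead, series)
  # census: adult counts from the plants (all placed in quadrat 1-1),
  # juvenile pulses two quarters before each cohort onset
  grid <- expand.grid(transect_id = 1:4, quadrat_id = 1:10, date = qdates)
  adults_at <- vapply(qdates, function(d)
    sum(recruit <= d + 1e-9 & last >= d - 1e-9), 0)
  juv_at <- ifelse(qdates %in% c(1999.75, 2004.5, 2004.75), 30, 0) +
    ifelse(qdates %in% c(2005.75, 2006.0), 6, 0)
  first_quad <- grid$transect_id == 1 & grid$quadrat_id == 1
  census <- data.frame(
    site_id = site, transect_id = grid$transect_id, quadrat_id = grid$quadrat_id,
    date = grid$date,
    macro_adult = ifelse(first_quad, adults_at[match(grid$date, qdates)], 0),
    macro_preadult = ifelse(first_quad, pmin(juv_at[match(grid$date, qdates)], 5), 0),
    macro_juvenile = ifelse(first_quad, juv_at[match(grid$date, qdates)], 0),
    stipe_count = ifelse(first_quad, 6 * adults_at[match(grid$date, qdates)], 0),
    stipitate = 1 + (grid$quadrat_id %% 3),
    laminate = grid$quadrat_id %% 2,
    desmarestia = ifelse(abs(grid$date - 2004.0) < 0.3, 4, 0),
    brown_turf = 0.1 + 0.3 * (grid$date > 2004),
    red_turf = 0.05 + 0.1 * (grid$date > 2004),
    articulated_coralline = 0.05,
    cystoseira = 0.02,
    psu_density = 0.2, rsu_density = 0.02)
  tdates <- seq(2000, 2009.9, by = 1 / 365.25)
  temperature <- data.frame(date = tdates,
    temperature = 14 + 2 * cos(2 * pi * ((tdates %% 1) - 0.7)))
  waves <- data.frame(date = tdates,
                      hs = 1 + 0.5 * cos(2 * pi * ((tdates %% 1) - 0.02)),
                      period = 10)
  truth <- list(windows = data.frame(site_id = site, episode = 1:2,
                                     start = c(2000.0, 2005.0),
                                     end = c(2000.5, 2006.5),
                                     pulsed = c(TRUE, FALSE)),
                membership = data.frame(plant_id = ids[seq_along(c(r1, r2))],
                                        episode = rep(1:2, c(length(r1), length(r2)))))
  list(census = validate_census(census), plants = plants,
       temperature = temperature, waves = waves,
       site_meta = data.frame(site_id = site, depth = 15,
                              year_established = 2000,
                              physiography = "fixture"),
       truth = truth)
}
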