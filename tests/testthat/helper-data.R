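# Small in-code fixture builders shared across test files.

# A plant table from vectors; stipe series default to one observation per
# census between recruit and last date, 6 stipes each (>= 4 at recruitment).
make_plants <- function(recruit, last, dead, site = "A",
                        stipes = NULL, ids = NULL) {
  n <- length(recruit)
  if (is.null(ids)) ids <- sprintf("%s-p%03d", site, seq_len(n))
  series <- lapply(seq_len(n), function(i) {
    d <- seq(recruit[i], max(recruit[i], last[i]), by = 0.25)
    s <- if (is.null(stipes)) rep(6, length(d)) else stipes[[i]]
    data.frame(date = d, stipes = s)
  })
  plant_table(ids, site, "1-1", recruit, last, dead, series)
}

# A minimal census table on the quarterly grid: one site, `nq` quadrats,
# with every count/cover zero unless overridden afterwards.
make_census <- function(dates, site = "A", nq = 4) {
  grid <- expand.grid(quadrat_id = seq_len(nq), date = dates)
  validate_census(data.frame(
    site_id = site, transect_id = 1, quadrat_id = grid$quadrat_id,
    date = grid$date,
    macro_adult = 0, macro_preadult = 0, macro_juvenile = 0,
    stipe_count = 0, stipitate = 0, laminate = 0, desmarestia = 0,
    brown_turf = 0, red_turf = 0, articulated_coralline = 0, cystoseira = 0,
    psu_density = 0, rsu_density = 0))
}

# Flat environmental series (no disturbance signal) covering [t0, t1].
make_env <- function(t0, t1, temp = 13) {
  d <- seq(t0, t1, by = 1 / 52)
  list(temperature = data.frame(date = d, temperature = temp),
       waves = data.frame(date = d, hs = 1, period = 10),
       waves_weekly = data.frame(date = d, hs = 1, period = 10,
                                 energy = wave_energy(1)))
}

# Cohort-parameter frames drawn from the additive models' own generative
# form, for parameter-recovery checks of the modeling module.
make_size_cohorts <- function(n = 150, seed = 1, b_ad = 0.015, b_und = -0.8) {
  set.seed(seed)
  ad <- runif(n, 0, 120)
  und <- runif(n, -1, 2)
  decade <- sample(c("1990s", "2000s", "2010s"), n, replace = TRUE)
  mu <- exp(3.2 + b_ad * ad + b_und * und)
  data.frame(N = rnbinom(n, mu = mu, size = 4), Ad = ad,
             understory_1yr = und, decade = decade, alive = FALSE)
}

make_longevity_cohorts <- function(n = 150, seed = 1, b_temp = -0.45,
                                   wave_effect = TRUE, urchin_effect = TRUE) {
  set.seed(seed)
  temp <- runif(n, 13, 20)
  wave <- runif(n, 500, 12000)
  psu <- rexp(n, 1 / 0.8)
  rsu <- rexp(n, 1 / 0.08)
  # unimodal wave response: rises to a plateau near 4000, falls past 6800
  gw <- ifelse(wave < 4000, wave / 4000,
               ifelse(wave < 6800, 1, pmax(0.1, 1 - (wave - 6800) / 6000)))
  eta <- 6 + b_temp * (temp - 16) +
    (if (wave_effect) 0.8 * gw else 0) +
    (if (urchin_effect) -0.25 * psu else 0)
  decade <- sample(c("1990s", "2000s", "2010s"), n, replace = TRUE)
  data.frame(life_mn = rnbinom(n, mu = exp(eta), size = 5) / 365.25,
             temp80 = temp, wave80 = wave, psu_density = psu,
             rsu_density = rsu, decade = decade, alive = FALSE)
}
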