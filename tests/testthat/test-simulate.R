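# Small-scale configurations keep the default test run fast; the full
# study-scale defaults are exercised by the acceptance script.
small_config <- function(seed, ...) {
  dots <- list(...)
  forcing <- utils::modifyList(list(cadence = 1 / 365.25),
                               dots$forcing %||% list())
  dots$forcing <- NULL
  do.call(simulation_config,
          c(list(n_sites = 2, years = c(2000, 2012), seed = seed,
                 established = c(2000, 2000), forcing = forcing), dots))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the same seed reproduces the simulation exactly", {
  a <- simulate_dataset(small_config(5))
  b <- simulate_dataset(small_config(5))
  expect_identical(as.data.frame(a$census), as.data.frame(b$census))
  expect_identical(a$plants$recruit_date, b$plants$recruit_date)
  expect_identical(a$truth$windows, b$truth$windows)
  c <- simulate_dataset(small_config(6))
  expect_false(identical(a$plants$recruit_date, c$plants$recruit_date))
})

test_that("a zero-noise configuration yields an exact seasonal sinusoid", {
  cfg <- small_config(1, forcing = list(cadence = 1 / 365.25, ar_sd = 0),
                      disturbances = data.frame(year = 2100, duration = 1,
                                                heat_anom = 0, wave_hs = 0))
  f <- simulate_forcing(cfg)
  expected <- cfg$forcing$temp_mean + cfg$forcing$temp_amp *
    cos(2 * pi * ((f$temperature$date %% 1) - cfg$forcing$temp_phase))
  expect_equal(f$temperature$temperature, expected)
})

test_that("a scheduled warm anomaly survives seasonal detrending", {
  cfg <- simulation_config(n_sites = 1, years = c(2000, 2015), seed = 2,
                           established = 2000,
                           forcing = list(cadence = 1 / 365.25, ar_sd = 0.2),
                           disturbances = data.frame(year = 2008.0, duration = 1,
                                                     heat_anom = 3, wave_hs = 0))
  f <- simulate_forcing(cfg)
  an <- seasonal_detrend(f$temperature)
  inwin <- an$date >= 2008 & an$date < 2009
  # sin^2 profile integrates to half the peak anomaly over the event year
  expect_gt(mean(an$anomaly[inwin]), 1.2)
  expect_gt(max(an$anomaly[inwin]), 2.5)
})

test_that("emitted tables validate and ground truth partitions the plants", {
  sim <- simulate_dataset(small_config(9))
  expect_s3_class(sim$census, "kelp_census")
  expect_s3_class(sim$plants, "kelp_plants")
  # membership covers every plant exactly once
  expect_setequal(sim$truth$membership$plant_id, sim$plants$plant_id)
  expect_false(anyDuplicated(sim$truth$membership$plant_id) > 0)
  # quadrat design: 4 transects x 10 quadrats at every census date
  percd <- table(sim$census$site_id, sim$census$date)
  expect_true(all(percd[percd > 0] == 40))
  # censored plants are exactly those alive at the final census
  expect_equal(sum(!sim$plants$dead),
               sum(sim$plants$last_date == max(sim$census$date)))
})

test_that("scheduled pulses are recovered exactly by window detection", {
  sched <- c(2001, 2003, 2005.25, 2007.5, 2009.75)
  cfg <- simulation_config(
    n_sites = 1, years = c(2000, 2012), seed = 31, established = 2000,
    forcing = list(cadence = 1 / 365.25),
    recruitment = list(mode = "scheduled", schedule = sched,
                       pulse_size = 40, pulse_span = 0.5))
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$windows), length(sched))
  w <- detect_cohort_windows(sim$plants)
  expect_equal(nrow(w), length(sched))
  p <- assign_plants(w, sim$plants)
  agree <- mean(as.integer(sub(".*-", "", p$cohort_id)) ==
                  sim$truth$membership$episode[match(p$plant_id,
                    sim$truth$membership$plant_id)])
  expect_equal(agree, 1)
})

test_that("a strong temperature-mortality coefficient shortens lifespans", {
  # identical runs except for the temperature coefficient of the hazard;
  # residual lifetime after the onset of a planted 3-degree heat event is
  # compared for the plants alive at that date
  base <- list(n_sites = 2, years = c(2000, 2010), seed = 13,
               established = c(2000, 2000),
               forcing = list(cadence = 1 / 365.25),
               disturbances = data.frame(year = 2005, duration = 1.5,
                                         heat_anom = 3, wave_hs = 0))
  run <- function(beta) simulate_dataset(do.call(simulation_config,
    c(base, list(mortality = list(baseline = 0.15, first_year = 0,
                                  beta_temp = beta)))))
  residual <- function(sim) {
    sel <- sim$plants$recruit_date <= 2004.75 & sim$plants$last_date >= 2004.75
    sim$plants$last_date[sel] - 2004.75
  }
  p <- suppressWarnings(stats::wilcox.test(residual(run(1.2)), residual(run(0)),
                                           alternative = "less")$p.value)
  expect_lt(p, 0.05)
})

test_that("without understory encroachment a pulsed regime stays pulsed", {
  sched <- c(2001, 2003.5, 2006)
  cfg <- simulation_config(
    n_sites = 1, years = c(2000, 2010), seed = 17, established = 2000,
    forcing = list(cadence = 1 / 365.25),
    recruitment = list(mode = "scheduled", schedule = sched,
                       pulse_size = 50, pulse_span = 0.5),
    understory = list(rate = 0, rate_post_shift = 0))
  sim <- simulate_dataset(cfg)
  w <- detect_cohort_windows(sim$plants)
  w <- classify_pulse(w, assign_plants(w, sim$plants))
  expect_true(all(w$pulsed))
  expect_true(all(sim$truth$windows$pulsed))
})

test_that("fixtures are deterministic with the documented structure", {
  f1 <- make_fixture("two_pulses")
  f2 <- make_fixture("two_pulses")
  expect_identical(f1, f2)
  expect_equal(nrow(f1$truth$windows), 2)
  expect_equal(f1$truth$windows$pulsed, c(TRUE, FALSE))
  w <- detect_cohort_windows(f1$plants)
  w <- classify_pulse(w, assign_plants(w, f1$plants))
  expect_equal(nrow(w), 2)
  expect_equal(w$pulsed, c(TRUE, FALSE))
  ct <- make_fixture("censored_tail")
  expect_equal(sum(!ct$plants$dead), 5)
  expect_error(make_fixture("nope"), "available")
})
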