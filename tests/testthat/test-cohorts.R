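test_that("recruitment runs split into windows at one-year gaps", {
  ev <- data.frame(site_id = "A",
                   date = c(2000.0, 2000.25, 2000.5, 2002.0, 2002.25))
  w <- detect_cohort_windows(ev)
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(2000.0, 2002.0))
  expect_equal(w$end, c(2000.5, 2002.25))
  expect_equal(w$n_recruits, c(3L, 2L))
  expect_false(any(w$extended))
  # no qualifying gap: one window, flagged extended past 18 months
  w1 <- detect_cohort_windows(data.frame(site_id = "A",
                                         date = c(2000.0, 2000.75, 2001.5, 2001.75)))
  expect_equal(nrow(w1), 1)
  expect_true(w1$extended)
  # a single recruit forms a singleton window
  ws <- detect_cohort_windows(data.frame(site_id = "A", date = 2003.5))
  expect_equal(ws$start, ws$end)
  expect_equal(nrow(detect_cohort_windows(data.frame(site_id = character(),
                                                     date = numeric()))), 0)
})

test_that("windows are maximal: merging or splitting violates the gap rule", {
  set.seed(21)
  for (rep in 1:25) {
    dates <- sort(2000 + 0.25 * sample.int(80, 25, replace = TRUE))
    w <- detect_cohort_windows(data.frame(site_id = "A", date = dates))
    if (nrow(w) > 1) {
      gaps <- w$start[-1] - w$end[-nrow(w)]
      expect_true(all(gaps >= 1 - 1e-9))
    }
    for (i in seq_len(nrow(w))) {
      inside <- unique(dates[dates >= w$start[i] & dates <= w$end[i]])
      if (length(inside) > 1)
        expect_true(max(diff(inside)) < 1)
    }
  }
})

test_that("plants are assigned to the window containing their recruit date", {
  plants <- make_plants(c(2000.0, 2000.5, 2002.0), c(2001, 2001, 2003),
                        c(TRUE, TRUE, TRUE))
  w <- detect_cohort_windows(plants)
  out <- assign_plants(w, plants)
  expect_equal(out$cohort_id, c("A-1", "A-1", "A-2"))
  # boundary dates are inclusive; roster sizes sum to assigned plants
  expect_equal(sum(w$n_recruits), nrow(plants))
  expect_error(assign_plants(rbind(w, within(w[1, ], {
    cohort_number <- 3; start <- 2000.25; end <- 2000.75
  })), plants), "overlapping")
})

test_that("the 80% first-year rule is inclusive at the boundary", {
  build <- function(k) {
    # k of 10 plants recruit within the first year of the window; the rest
    # follow within the same window (all inter-event gaps < 1 yr)
    r <- c(rep(2000.0, k - 1), 2000.5, rep(2001.25, 10 - k))
    make_plants(r, r + 1, rep(TRUE, 10))
  }
  for (k in c(7, 8, 9)) {
    p <- build(k)
    w <- classify_pulse(detect_cohort_windows(p), assign_plants(detect_cohort_windows(p), p))
    expect_equal(w$pulsed, k >= 8, info = sprintf("%d of 10 in first year", k))
  }
})

test_that("pulse classification is invariant to time translation", {
  set.seed(8)
  r <- 2000 + 0.25 * sample.int(10, 12, replace = TRUE)
  for (shift in c(0, 7.25, -3.5)) {
    p <- make_plants(r + shift, r + shift + 0.5, rep(TRUE, 12))
    w <- detect_cohort_windows(p)
    w <- classify_pulse(w, assign_plants(w, p))
    if (shift == 0) base <- w$pulsed else expect_equal(w$pulsed, base)
  }
})

test_that("blending needs a surviving plant from an earlier cohort at onset", {
  # predecessor dies two years before the successor: not blended
  p1 <- make_plants(c(2000, 2000, 2004), c(2001, 2001.5, 2005), rep(TRUE, 3))
  w1 <- detect_blending(detect_cohort_windows(p1), p1)
  expect_equal(w1$blended, c(FALSE, FALSE))
  # one survivor observed at the successor's onset: blended
  p2 <- make_plants(c(2000, 2000, 2004), c(2001, 2004.25, 2005), rep(TRUE, 3))
  w2 <- detect_blending(detect_cohort_windows(p2), p2)
  expect_equal(w2$blended, c(FALSE, TRUE))
})

test_that("juvenile response is judged against the pre-die-off baseline", {
  # predecessor: 10 plants dead by 2002.0 (95% die-off mid-2001);
  # successor onset 2004
  r <- rep(2000, 10)
  last <- c(rep(2001.5, 9), 2001.75)
  p <- make_plants(c(r, rep(2004, 5)), c(last, rep(2005, 5)), rep(TRUE, 15))
  w <- detect_cohort_windows(p)
  p <- assign_plants(w, p)
  dates <- seq(2000, 2005, by = 0.25)
  cen <- make_census(dates, nq = 2)
  t95 <- 2001.75 + 0.125  # midpoint death of the last plant
  # juveniles at the first census after the die-off
  cen$macro_juvenile[cen$date == 2002.0 & cen$quadrat_id == 1] <- 20
  wj <- juvenile_response(w, p, cen)
  expect_equal(wj$juvenile_response, c(NA, TRUE))
  # no juveniles for a year after the die-off -> FALSE
  wq <- juvenile_response(w, p, make_census(dates, nq = 2))
  expect_equal(wq$juvenile_response, c(NA, FALSE))
  # predecessor never reaches 95% mortality (censored tail) -> not applicable
  pc <- make_plants(c(r, rep(2004, 5)), c(last, rep(2005, 5)),
                    c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5)))
  pc <- assign_plants(w, pc)
  wn <- juvenile_response(w, pc, cen)
  expect_true(is.na(wn$juvenile_response[2]))
})

test_that("cohort parameters match hand computations on a toy cohort", {
  # three plants each observed exactly once: singles = N = 3
  p <- make_plants(rep(2001, 3), rep(2001, 3), rep(TRUE, 3))
  w <- detect_cohort_windows(p)
  p <- assign_plants(w, p)
  cen <- make_census(seq(2000, 2003, 0.25), nq = 2)
  env <- make_env(1999, 2005)
  ch <- suppressWarnings(cohort_parameters(w, p, cen, env$temperature, env$waves_weekly))
  expect_equal(ch$N, 3)
  expect_equal(ch$singles, 3)
  # a plant with stipe series (4, 9, 6) contributes its max, 9
  p2 <- make_plants(c(2001, 2001), c(2001.5, 2001.5), c(TRUE, TRUE),
                    stipes = list(c(4, 9, 6), c(5, 5, 5)))
  w2 <- detect_cohort_windows(p2)
  ch2 <- suppressWarnings(cohort_parameters(w2, assign_plants(w2, p2), cen,
                           env$temperature, env$waves_weekly))
  expect_equal(ch2$st_max_mn, (9 + 5) / 2)
  # lifespans 1.0 and 3.0 yr uncensored: mean 2.0; the median is the first
  # event time where S drops to 0.5 (the documented <= convention)
  p3 <- make_plants(c(2001, 2001), c(2002, 2004), c(TRUE, TRUE))
  w3 <- detect_cohort_windows(p3)
  ch3 <- suppressWarnings(cohort_parameters(w3, assign_plants(w3, p3),
                           make_census(seq(2000, 2005, 0.25), nq = 2),
                           env$temperature, env$waves_weekly,
                           convention = "last-seen"))
  expect_equal(ch3$life_mn, 2.0)
  expect_equal(ch3$km_q50, 1.0)
  expect_equal(ch3$km_q95, 3.0)
  expect_equal(ch3$decade, "2000s")
})

test_that("context-window counts and prior adults enter the parameter vector", {
  # cohort 2 at 2004; 12 juveniles and 4 pre-adults in the prior year;
  # 2 adults of cohort 1 still alive within the year before onset
  p <- make_plants(c(2000, 2000, 2000, 2004, 2004),
                   c(2003.25, 2003.5, 2001, 2005, 2005.5),
                   rep(TRUE, 5))
  w <- detect_cohort_windows(p)
  p <- assign_plants(w, p)
  dates <- seq(2000, 2006, 0.25)
  cen <- make_census(dates, nq = 2)
  cen$macro_juvenile[cen$date == 2003.5 & cen$quadrat_id == 1] <- 12
  cen$macro_preadult[cen$date == 2003.75 & cen$quadrat_id == 1] <- 4
  env <- make_env(1999, 2007)
  ch <- suppressWarnings(cohort_parameters(w, p, cen, env$temperature, env$waves_weekly))
  expect_equal(ch$juveniles_1yr[2], 12)
  expect_equal(ch$PA[2], 4)
  expect_equal(ch$Ad[2], 2)
  expect_equal(ch$Ad[1], 0)
  # flat forcing: the covariate quantiles reproduce the constants
  expect_equal(ch$temp80[1], 13)
  expect_equal(ch$wave80[1], wave_energy(1))
})

test_that("rule-based mortality attribution fires the documented rules", {
  roster <- make_plants(rep(2000, 10), rep(2001, 10), rep(TRUE, 10))
  dates <- seq(1999, 2003, by = 1 / 52)
  calm <- data.frame(date = dates, energy = 1000)
  cool <- data.frame(date = dates, temperature = 13)
  cen0 <- make_census(seq(2000, 2002, 0.25), nq = 2)
  # a storm over the terminal phase
  stormy <- calm; stormy$energy[abs(dates - 2001.1) < 0.05] <- 8000
  expect_equal(attribute_mortality(roster, cool, stormy, cen0, "A"), "waves")
  # nothing fires
  expect_equal(attribute_mortality(roster, cool, calm, cen0, "A"), "not known")
  # purple urchins above 2.5 per m2
  cenu <- cen0; cenu$psu_density <- 3.0
  expect_equal(attribute_mortality(roster, cool, calm, cenu, "A"), "sea urchins")
  # warm terminal phase
  hot <- cool; hot$temperature[dates > 2000.9] <- 18
  expect_equal(attribute_mortality(roster, hot, calm, cen0, "A"), "heat")
  expect_equal(attribute_mortality(roster, hot, stormy, cen0, "A"), "heat/waves")
  # small cohorts short-circuit
  expect_equal(attribute_mortality(roster[1:3, ], hot, stormy, cen0, "A"),
               "small cohort")
})

test_that("the demographic summary reports the Table-style proportions", {
  ch <- data.frame(pulsed = c(TRUE, TRUE, FALSE, TRUE),
                   blended = c(FALSE, TRUE, TRUE, FALSE),
                   juvenile_response = c(NA, TRUE, FALSE, TRUE),
                   mortality_cause = c("waves", "heat", "not known", "waves"),
                   alive = c(FALSE, FALSE, FALSE, TRUE))
  s <- demographic_summary(ch)
  expect_equal(s$proportion[s$category == "Pulsed"], 0.75)
  expect_equal(s$proportion[s$category == "Trickled"], 0.25)
  expect_equal(s$proportion[s$category == "Within 3 months after previous cohort"],
               2 / 3)
  mc <- s[s$event == "Mortality cause (rule-based)", ]
  expect_equal(sum(mc$proportion), 1)
})
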