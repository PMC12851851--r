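guild_cols <- c("macro_adult", "stipe_count", "macro_juvenile", "stipitate",
                "laminate", "brown_turf", "red_turf", "articulated_coralline",
                "desmarestia")

test_that("guild pooling sums life stages and turf components", {
  cen <- make_census(2000, nq = 2)
  cen$macro_juvenile <- c(3, 0)
  cen$macro_preadult <- c(2, 0)
  cen$brown_turf <- c(0.2, 0)
  cen$cystoseira <- c(0.1, 0)
  g <- pool_guilds(cen)
  expect_equal(g$macro_juvenile, c(5, 0))
  expect_equal(g$brown_turf, c(0.3, 0))
  expect_equal(unlist(g[2, guild_cols]), setNames(rep(0, 9), guild_cols))
  expect_error(pool_guilds(cen[, -match("cystoseira", names(cen))]), "cystoseira")
})

test_that("z-score scaling uses the sample (n-1) standard deviation", {
  cen <- make_census(c(2000, 2000.25), nq = 1)
  cen$macro_adult <- c(0, 2)
  cen$stipe_count <- c(0, 8)
  g <- pool_guilds(cen)
  expect_warning(s <- scale_features(g), "zero-variance")
  expect_equal(s$macro_adult, c(-1, 1) / sqrt(2))  # +-0.707
  expect_equal(s$macro_juvenile, c(0, 0))          # constant -> zeros
  # re-applying stored parameters reproduces the training transform
  s2 <- scale_features(g, params = attr(s, "scaling"))
  expect_equal(s2$macro_adult, s$macro_adult)
  # range scaling maps the observed range onto [0, 1]
  expect_warning(r <- scale_features(g, method = "range"))
  expect_equal(r$macro_adult, c(0, 1))
})

test_that("k-medoids separates well-separated clouds and is seeded", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
  st <- cluster_states(x, k = 2, seed = 11)
  expect_equal(length(unique(st$assignment[1:20])), 1)
  expect_equal(length(unique(st$assignment[21:40])), 1)
  expect_false(st$assignment[1] == st$assignment[40])
  st2 <- cluster_states(x, k = 2, seed = 11)
  expect_identical(st$assignment, st2$assignment)
  # n = k: every point its own medoid, zero cost
  xx <- matrix(runif(6), ncol = 2)
  expect_equal(cluster_states(xx, k = 3, seed = 1)$cost, 0)
  expect_error(cluster_states(xx, k = 4, seed = 1), "clusters")
  xx[1] <- NA
  expect_error(cluster_states(xx, k = 2, seed = 1), "non-finite")
})

test_that("CLARA output on a 12-point set attains the exhaustive PAM optimum", {
  set.seed(9)
  x <- matrix(c(runif(8, 0, 1), runif(8, 4, 5), runif(8, 9, 10)), ncol = 2,
              byrow = TRUE)[1:12, ]
  st <- cluster_states(x, k = 3, seed = 2)
  expect_equal(st$cost, pam_brute_cost(x, 3))
  # every point is assigned to its Manhattan-nearest medoid
  d <- l1_dist(x, st$medoids)
  expect_equal(st$assignment, max.col(-d, ties.method = "first"))
})

test_that("subsampled CLARA still assigns points to their nearest medoid", {
  set.seed(4)
  x <- matrix(rnorm(600), ncol = 3)
  st <- cluster_states(x, k = 4, seed = 5, n_samples = 3, sample_size = 30)
  d <- l1_dist(x, st$medoids)
  expect_equal(st$assignment, max.col(-d, ties.method = "first"))
  expect_equal(st$cost, sum(d[cbind(1:200, st$assignment)]))
})

test_that("gap statistic recovers planted cluster counts", {
  set.seed(7)
  x3 <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
              matrix(rnorm(60, 5, 0.3), ncol = 2),
              matrix(rnorm(60, c(0, 10), 0.3), ncol = 2, byrow = TRUE))
  g3 <- gap_statistic(x3, k_max = 5, B = 20, seed = 1)
  expect_equal(g3$k_opt, 3)
  expect_equal(nrow(g3$table), 5)
  blob <- matrix(runif(120), ncol = 2)
  expect_equal(gap_statistic(blob, k_max = 4, B = 20, seed = 2)$k_opt, 1)
  expect_error(gap_statistic(blob, k_max = 4, B = 5), "B >= 10")
})

test_that("the five community states are labeled from their medoids", {
  med <- rbind(
    Kelp = c(2.0, 2.2, -0.2, -0.5, -0.5, -0.6, -0.4, -0.3, -0.2),
    Disturbed = c(-0.8, -0.9, 0.1, -0.2, -0.1, 0.0, 0.1, 0.0, 2.5),
    Recovery = c(-0.3, -0.4, 2.4, 0.2, 0.1, 0.8, 0.2, 0.1, 0.3),
    Mixed = c(0.6, 0.5, 0.3, 0.4, 0.3, 0.3, 0.2, 0.2, 0.0),
    Understory = c(-0.9, -1.0, -0.5, 1.8, 1.5, 1.2, 1.0, 0.9, -0.2))
  colnames(med) <- guild_cols
  st <- structure(list(medoids = med, k = 5), class = "kelp_states")
  labelled <- label_states(st)
  expect_equal(labelled$labels, rownames(med))
  # identical medoids cannot be labeled bijectively
  med2 <- med; med2[2, ] <- med2[3, ]
  st2 <- structure(list(medoids = med2, k = 5), class = "kelp_states")
  expect_error(label_states(st2), "bijection")
  expect_error(label_states(structure(list(medoids = med[1:4, ], k = 4),
                                      class = "kelp_states")), "k = 5")
})

test_that("state timelines are per-site quadrat fractions summing to one", {
  df <- data.frame(site_id = "A", date = 2000,
                   state = rep(c("Kelp", "Understory"), c(30, 10)))
  tl <- state_timeline(df)
  expect_equal(tl$fraction[tl$state == "Kelp"], 0.75)
  expect_equal(tl$fraction[tl$state == "Understory"], 0.25)
  one <- state_timeline(data.frame(site_id = "A", date = 2000, state = "Mixed"))
  expect_equal(one$fraction, 1)
  # sums to 1 at every site-date of a random timeline
  set.seed(1)
  big <- data.frame(site_id = sample(c("A", "B"), 200, TRUE),
                    date = sample(c(2000, 2000.25, 2000.5), 200, TRUE),
                    state = sample(c("Kelp", "Mixed", "Understory"), 200, TRUE))
  tl2 <- state_timeline(big)
  sums <- tapply(tl2$fraction, paste(tl2$site_id, tl2$date), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)))
})

test_that("persistent dominant-state changes are detected, excursions ignored", {
  dates <- seq(2000, 2009.75, by = 0.25)
  mk <- function(states) do.call(rbind, lapply(seq_along(dates), function(i)
    data.frame(site_id = "A", date = dates[i],
               state = c("Kelp", "Understory"),
               fraction = if (states[i] == "Kelp") c(1, 0) else c(0, 1),
               n_quadrats = 40)))
  clean <- mk(rep(c("Kelp", "Understory"), each = 20))
  ev <- detect_state_shifts(clean)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$from_state, "Kelp")
  expect_equal(ev$to_state, "Understory")
  expect_equal(ev$date, 2005)
  # a single-census excursion shorter than the persistence window: no event
  burp <- rep("Kelp", 40); burp[20] <- "Understory"
  expect_equal(nrow(detect_state_shifts(mk(burp))), 0)
  # constant timeline: no events
  expect_equal(nrow(detect_state_shifts(mk(rep("Kelp", 40)))), 0)
})

test_that("planted regime switches are recovered exactly", {
  dates <- seq(2000, 2019.75, by = 0.25)
  truth <- rep(c("Kelp", "Understory", "Recovery", "Kelp"), c(24, 16, 20, 20))
  tl <- do.call(rbind, lapply(seq_along(dates), function(i) {
    fr <- c(Kelp = 0.1, Understory = 0.1, Recovery = 0.1)
    fr[truth[i]] <- 0.8
    data.frame(site_id = "A", date = dates[i], state = names(fr),
               fraction = unname(fr), n_quadrats = 40)
  }))
  ev <- detect_state_shifts(tl)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$to_state, c("Understory", "Recovery", "Kelp"))
})
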