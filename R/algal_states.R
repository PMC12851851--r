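## Algal community states: guild pooling, feature scaling, CLARA k-medoids
## clustering (Manhattan distance), gap-statistic choice of k, five-state
## labeling, per-site state timelines and persistent state shifts.

.guild_cols <- c("macro_adult", "stipe_count", "macro_juvenile", "stipitate",
                 "laminate", "brown_turf", "red_turf", "articulated_coralline",
                 "desmarestia")
.state_names <- c("Kelp", "Disturbed", "Recovery", "Mixed", "Understory")

#' Pool census taxa into canopy guilds
#'
#' Builds the nine-feature guild vector per quadrat-census used for
#' community-state clustering: adult Macrocystis density, total stipe
#' count, juveniles (all life stages prior to adulthood, i.e. juveniles
#' plus pre-adults), stipitate kelps, laminate kelps, brown turf
#' (Dictyotales plus Cystoseira osmundacea, which grows as a low turf),
#' red turf, articulated corallines, and the early-successional
#' Desmarestia ligulata as its own category.
#'
#' @param census a validated census table ([load_census()]).
#' @return data frame of census keys plus the nine unscaled guild columns.
#' @export
pool_guilds <- function(census) {
  need <- c(.census_keys, "macro_adult", "macro_preadult", "macro_juvenile",
            "stipe_count", "stipitate", "laminate", "brown_turf", "red_turf",
            "articulated_coralline", "cystoseira", "desmarestia")
  missing <- setdiff(need, names(census))
  if (length(missing))
    stopf("census lacks guild components: %s", paste(missing, collapse = ", "))
  out <- as.data.frame(census)[, .census_keys]
  out$macro_adult <- census$macro_adult
  out$stipe_count <- census$stipe_count
  out$macro_juvenile <- census$macro_juvenile + census$macro_preadult
  out$stipitate <- census$stipitate
  out$laminate <- census$laminate
  out$brown_turf <- census$brown_turf + census$cystoseira
  out$red_turf <- census$red_turf
  out$articulated_coralline <- census$articulated_coralline
  out$desmarestia <- census$desmarestia
  out
}

#' Scale guild features
#'
#' Per-feature standardization over all quadrat-censuses pooled across
#' sites and times. `"zscore"` (default) centres to mean 0 and scales to
#' unit sample standard deviation (n-1 denominator); `"range"` maps the
#' observed range to \[0, 1\]. Zero-variance features are set to 0 and
#' flagged with a warning. Scaling parameters are stored so the transform
#' can be re-applied to new data.
#'
#' @param guilds output of [pool_guilds()] (or any data frame containing
#'   the guild columns).
#' @param method `"zscore"` or `"range"`.
#' @param params optional stored parameters from a previous call; when
#'   given, they are applied unchanged.
#' @return the input with guild columns replaced by scaled values;
#'   attribute `"scaling"` holds `list(method, center, scale)`.
#' @export
scale_features <- function(guilds, method = c("zscore", "range"), params = NULL) {
  method <- match.arg(method)
  x <- as.matrix(guilds[, .guild_cols])
  if (is.null(params)) {
    if (method == "zscore") {
      center <- colMeans(x)
      scale <- apply(x, 2, stats::sd)
    } else {
      center <- apply(x, 2, min)
      scale <- apply(x, 2, max) - center
    }
    degenerate <- scale == 0 | !is.finite(scale)
    if (any(degenerate)) {
      warnf("zero-variance feature(s) set to 0: %s",
            paste(.guild_cols[degenerate], collapse = ", "))
      scale[degenerate] <- Inf  # maps the feature to 0
    }
    params <- list(method = method, center = center, scale = scale)
  }
  scaled <- sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
  out <- guilds
  out[, .guild_cols] <- scaled
  attr(out, "scaling") <- params
  out
}

## Guild feature matrix from a data frame or matrix input.
guild_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (all(.guild_cols %in% names(x))) return(as.matrix(x[, .guild_cols]))
  as.matrix(x[, vapply(x, is.numeric, TRUE), drop = FALSE])
}

## Total Manhattan cost and nearest-medoid assignment of all points.
medoid_cost <- function(x, medoids) {
  d <- manhattan_dist(x, medoids)
  assign <- max.col(-d, ties.method = "first")
  list(assignment = assign, cost = sum(d[cbind(seq_len(nrow(x)), assign)]))
}

#' Cluster quadrat-censuses into community states (CLARA k-medoids)
#'
#' CLARA-style k-medoids with Manhattan distance: `n_samples` subsamples
#' of size `sample_size` are each clustered by PAM (build + swap,
#' `cluster::pam`), and the medoid set with the lowest total Manhattan
#' distance of *all* points to their nearest medoid is kept. When the data
#' fit in one sample, this reduces to a single exact PAM run.
#'
#' @param x scaled guild data frame ([scale_features()]) or numeric matrix.
#' @param k number of clusters (>= 1).
#' @param seed RNG seed for the subsampling (required for reproducibility).
#' @param n_samples number of subsamples (classic default 5).
#' @param sample_size subsample size; default `min(n, 40 + 2 * k)`.
#' @return an object of class `kelp_states`: medoid matrix (`k` rows),
#'   integer `assignment` per row of `x`, total `cost`, and the census
#'   keys when `x` carries them.
#' @export
cluster_states <- function(x, k, seed = 1, n_samples = 5, sample_size = NULL) {
  keys <- if (is.data.frame(x) && all(.census_keys %in% names(x)))
    x[, .census_keys] else NULL
  m <- guild_matrix(x)
  n <- nrow(m)
  if (k < 1) stopf("k must be >= 1")
  if (n < k) stopf("cannot form %d clusters from %d points", k, n)
  if (any(!is.finite(m))) stopf("non-finite feature values")
  if (is.null(sample_size)) sample_size <- min(n, 40 + 2 * k)
  sample_size <- max(sample_size, k)
  if (n == k) {
    # degenerate: every point is its own medoid at zero cost
    ev <- medoid_cost(m, m)
    return(structure(list(medoids = m, medoid_rows = seq_len(n),
                          assignment = ev$assignment, cost = ev$cost,
                          k = k, n = n, keys = keys, labels = NULL),
                     class = "kelp_states"))
  }

  pam_medoids <- function(rows, init = NULL) {
    if (length(rows) == k) return(rows)
    fit <- cluster::pam(m[rows, , drop = FALSE], k, metric = "manhattan",
                        medoids = init, cluster.only = FALSE,
                        keep.diss = FALSE, keep.data = FALSE)
    rows[fit$id.med]
  }

  best <- NULL
  keep_best <- function(med) {
    ev <- medoid_cost(m, m[med, , drop = FALSE])
    if (is.null(best) || ev$cost < best$eval$cost)
      best <<- list(medoid_rows = med, eval = ev)
  }
  with_seed(seed, {
    if (sample_size >= n) {
      # whole data in one sample: the build-initialized PAM run plus random
      # restarts of the swap phase (more on small instances, where restarts
      # are cheap and reliably reach the global optimum), best cost kept
      keep_best(pam_medoids(seq_len(n)))
      restarts <- if (n <= 50) max(n_samples - 1, 2 * n) else n_samples - 1
      for (s in seq_len(max(0, restarts)))
        keep_best(pam_medoids(seq_len(n), init = sample.int(n, k)))
    } else {
      for (s in seq_len(n_samples))
        keep_best(pam_medoids(sort(sample.int(n, sample_size))))
    }
  })
  structure(list(medoids = m[best$medoid_rows, , drop = FALSE],
                 medoid_rows = best$medoid_rows,
                 assignment = best$eval$assignment,
                 cost = best$eval$cost, k = k, n = n,
                 keys = keys, labels = NULL),
            class = "kelp_states")
}

#' @export
print.kelp_states <- function(x, ...) {
  cat(sprintf("k-medoids community states: k = %d, n = %d, total Manhattan cost = %.3f\n",
              x$k, x$n, x$cost))
  cat("cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  if (!is.null(x$labels))
    cat("labels:", paste(seq_len(x$k), x$labels, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Gap statistic for the number of community states
#'
#' For each `k` in `1..k_max`, the within-cluster dispersion `W_k` is the
#' total Manhattan distance of points to their medoid; the gap is
#' `mean(log W*_k) - log W_k` over `B` uniform reference datasets drawn
#' over the per-feature observed ranges. The selected `k` is the smallest
#' with `gap(k) >= gap(k+1) - s(k+1)` (one-standard-error rule), where
#' `s(k) = sd(log W*_k) * sqrt(1 + 1/B)`.
#'
#' @inheritParams cluster_states
#' @param k_max largest number of clusters to consider.
#' @param B number of reference draws (>= 10).
#' @return list with `table` (k, logW, gap, s) and `k_opt`.
#' @export
gap_statistic <- function(x, k_max, B = 50, seed = 1, n_samples = 5,
                          sample_size = NULL) {
  if (B < 10) stopf("gap statistic needs B >= 10 reference draws")
  m <- guild_matrix(x)
  rng_lo <- apply(m, 2, min); rng_hi <- apply(m, 2, max)
  logW <- function(data, sd) vapply(seq_len(k_max), function(k)
    log(max(cluster_states(data, k, seed = sd + k, n_samples = n_samples,
                           sample_size = sample_size)$cost, 1e-12)), 0)
  obs <- logW(m, child_seed(seed, 1))
  ref <- with_seed(child_seed(seed, 2), {
    vapply(seq_len(B), function(b) {
      u <- matrix(stats::runif(length(m)), nrow(m), ncol(m))
      r <- sweep(sweep(u, 2, rng_hi - rng_lo, "*"), 2, rng_lo, "+")
      logW(r, child_seed(seed, 100 + b))
    }, numeric(k_max))
  })
  gap <- rowMeans(ref) - obs
  s <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / B)
  k_opt <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) { k_opt <- k; break }
  }
  list(table = data.frame(k = seq_len(k_max), logW = obs, gap = gap, s = s),
       k_opt = k_opt)
}

#' Label the five community states from their medoids
#'
#' Deterministic rules on the (scaled) medoid guild features, applied in
#' priority order: *Kelp* is the medoid with the largest adult + stipe
#' score (a well-developed giant kelp stand); among the rest, *Recovery*
#' has the largest juvenile score (post-disturbance recruitment);
#' *Disturbed* the largest Desmarestia score (early-successional pioneer);
#' of the remaining two, *Understory* has the larger pooled
#' stipitate + laminate + turf + coralline score and *Mixed* is the
#' remainder. Exact ties between identical medoids are an error.
#'
#' @param states a `kelp_states` object with `k = 5`.
#' @return the object with `labels` set (character vector over clusters).
#' @export
label_states <- function(states) {
  if (states$k != 5) stopf("state labeling is defined for k = 5 (got k = %d)", states$k)
  med <- states$medoids
  score <- cbind(
    kelp = med[, "macro_adult"] + med[, "stipe_count"],
    recovery = med[, "macro_juvenile"],
    disturbed = med[, "desmarestia"],
    understory = med[, "stipitate"] + med[, "laminate"] + med[, "brown_turf"] +
      med[, "red_turf"] + med[, "articulated_coralline"])
  labels <- rep(NA_character_, 5)
  remaining <- seq_len(5)
  take <- function(col) {
    v <- score[remaining, col]
    top <- which(v == max(v))
    if (length(top) > 1) {
      rows <- med[remaining[top], , drop = FALSE]
      if (any(duplicated(rows)))
        stopf("state labeling is not a bijection: identical medoids tie on '%s'", col)
    }
    pick <- remaining[top[1]]
    remaining <<- setdiff(remaining, pick)
    pick
  }
  labels[take("kelp")] <- "Kelp"
  labels[take("recovery")] <- "Recovery"
  labels[take("disturbed")] <- "Disturbed"
  labels[take("understory")] <- "Understory"
  labels[remaining] <- "Mixed"
  states$labels <- labels
  states
}

#' Per-site state fractions over time
#'
#' Characterizes algal states as the fraction of a site's quadrats in each
#' cluster at each census date; quadrats not sampled at a date are
#' excluded from the denominator.
#'
#' @param states a `kelp_states` object carrying census keys, or a data
#'   frame with `site_id`, `date`, and `state` columns.
#' @return a `kelp_timeline` data frame: `site_id`, `date`, `state`,
#'   `fraction`, `n_quadrats`.
#' @export
state_timeline <- function(states) {
  if (inherits(states, "kelp_states")) {
    if (is.null(states$keys))
      stopf("state assignments carry no census keys; cluster a keyed guild table")
    lab <- if (!is.null(states$labels)) states$labels[states$assignment]
           else as.character(states$assignment)
    df <- data.frame(site_id = states$keys$site_id, date = states$keys$date,
                     state = lab)
  } else df <- states
  levels <- sort(unique(df$state))
  out <- do.call(rbind, lapply(split(df, list(df$site_id, df$date), drop = TRUE),
    function(g) {
      tab <- table(factor(g$state, levels = levels))
      data.frame(site_id = g$site_id[1], date = g$date[1], state = levels,
                 fraction = as.numeric(tab) / nrow(g), n_quadrats = nrow(g))
    }))
  out <- out[order(out$site_id, out$date, out$state), ]
  rownames(out) <- NULL
  class(out) <- unique(c("kelp_timeline", class(out)))
  out
}

#' Detect persistent shifts of the dominant algal state
#'
#' A site is "in" state S at a census when S has the largest quadrat
#' fraction and that fraction is at least `dominance_threshold`. A run of
#' consecutive censuses in the same state is *established* when it spans
#' at least `persistence` years (a run of one quarterly census spans
#' 0.25 yr). A shift event is emitted whenever the established state
#' changes; excursions too short to establish are ignored.
#'
#' @param timeline a `kelp_timeline` data frame ([state_timeline()]).
#' @param dominance_threshold minimum fraction for dominance (default 0.4).
#' @param persistence minimum run span in years (default 1).
#' @return data frame `site_id`, `date` (start of the new established
#'   run), `from_state`, `to_state`.
#' @export
detect_state_shifts <- function(timeline, dominance_threshold = 0.4,
                                persistence = 1) {
  events <- list()
  for (site in unique(timeline$site_id)) {
    tl <- timeline[timeline$site_id == site, ]
    dates <- sort(unique(tl$date))
    if (length(dates) < 2) next
    cadence <- stats::median(diff(dates))
    dom <- vapply(dates, function(d) {
      g <- tl[tl$date == d, ]
      i <- which.max(g$fraction)
      if (g$fraction[i] >= dominance_threshold) g$state[i] else NA_character_
    }, "")
    r <- rle(dom)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    span <- dates[ends] - dates[starts] + cadence
    est <- which(!is.na(r$values) & span >= persistence - 1e-9)
    if (length(est) < 2) next
    for (j in seq_along(est)[-1]) {
      a <- est[j - 1]; b <- est[j]
      if (r$values[a] != r$values[b])
        events[[length(events) + 1]] <- data.frame(
          site_id = site, date = dates[starts[b]],
          from_state = r$values[a], to_state = r$values[b])
    }
  }
  if (!length(events))
    return(data.frame(site_id = character(), date = numeric(),
                      from_state = character(), to_state = character()))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}
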