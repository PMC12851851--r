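# Independent oracles, deliberately written without reusing any package
# internals.

# Product-limit estimate by direct risk-set enumeration: at each distinct
# event time, n_i = subjects with duration >= t (censorings at t remain at
# risk: events precede censorings), d_i = events at t.
km_brute <- function(durations, events) {
  times <- sort(unique(durations[events]))
  s <- 1
  surv <- numeric(length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    n_i <- sum(durations >= t - 1e-12)
    d_i <- sum(events & abs(durations - t) < 1e-12)
    s <- s * (1 - d_i / n_i)
    surv[j] <- s
  }
  data.frame(time = times, surv = surv)
}

# Evaluate expr under a local RNG state.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

l1_dist <- function(x, y) {
  out <- matrix(0, nrow(x), nrow(y))
  for (j in seq_len(nrow(y)))
    out[, j] <- rowSums(abs(sweep(x, 2, y[j, ], "-")))
  out
}

# Exhaustive k-medoids optimum: minimum over all size-k medoid subsets of
# the total Manhattan distance of every point to its nearest medoid.
pam_brute_cost <- function(x, k) {
  x <- as.matrix(x)
  combs <- utils::combn(nrow(x), k)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    d <- l1_dist(x, x[combs[, j], , drop = FALSE])
    best <- min(best, sum(apply(d, 1, min)))
  }
  best
}
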