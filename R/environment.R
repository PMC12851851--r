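## Bottom-temperature and wave preprocessing, and windowed covariate
## extraction for the cohort longevity model.

## Pick the measurement column of an environment-like series.
env_value_col <- function(series) {
  for (col in c("temperature", "anomaly", "energy", "hs", "value"))
    if (col %in% names(series)) return(col)
  stopf("no recognised value column in series (have: %s)",
        paste(names(series), collapse = ", "))
}

#' Linearly interpolate short gaps in an environment series
#'
#' The series is laid onto its nominal grid (cadence inferred as the median
#' timestamp spacing unless given). Interior runs of missing values whose
#' span is at most `max_gap` are filled by linear interpolation; longer
#' gaps are left missing and reported via the `"long_gaps"` attribute.
#'
#' @param series data frame with `date` (decimal years) and one value
#'   column; missing observations may be absent rows or `NA` values.
#' @param max_gap longest gap to fill, in years (default one month).
#' @param cadence nominal spacing in years; default inferred
#'   (3-h cadence = 1/2922 yr).
#' @return the gridded series with short gaps filled; attribute
#'   `"long_gaps"` holds a data frame of unfilled intervals.
#' @export
interpolate_gaps <- function(series, max_gap = 1 / 12, cadence = NULL) {
  if (nrow(series) == 0) stopf("empty environment series")
  col <- env_value_col(series)
  ord <- order(series$date)
  t <- series$date[ord]; v <- series[[col]][ord]
  keep <- !is.na(v)
  if (!any(keep)) stopf("environment series has no observed values")
  if (is.null(cadence)) cadence <- stats::median(diff(t))
  grid <- seq(min(t), max(t) + cadence / 2, by = cadence)
  idx <- round((t[keep] - grid[1]) / cadence) + 1
  gv <- rep(NA_real_, length(grid))
  gv[idx] <- v[keep]
  miss <- is.na(gv)
  long_gaps <- data.frame(from = numeric(), to = numeric())
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    filled <- stats::approx(grid[!miss], gv[!miss], xout = grid, rule = 1)$y
    for (i in which(r$values)) {
      span <- (r$lengths[i] + 1) * cadence
      s <- starts[i]; e <- ends[i]
      if (s == 1 || e == length(grid)) next  # edge gaps cannot be interpolated
      if (span <= max_gap) {
        gv[s:e] <- filled[s:e]
      } else {
        long_gaps <- rbind(long_gaps, data.frame(from = grid[s], to = grid[e]))
      }
    }
  }
  out <- data.frame(date = grid)
  out[[col]] <- gv  # long gaps stay NA
  attr(out, "kind") <- attr(series, "kind")
  attr(out, "long_gaps") <- long_gaps
  out
}

#' Seasonally detrend a temperature series
#'
#' Removes the mean seasonal cycle: a day-of-year climatology (across-year
#' mean per day of year, smoothed by a centred circular moving mean of
#' width `smooth_window` days with triangular weights, which suppresses
#' day-to-day sampling noise while attenuating the annual harmonic itself
#' by well under 1%) is subtracted from every observation.
#'
#' @param series data frame with `date` and `temperature`.
#' @param smooth_window climatology smoothing window in days (default 31).
#' @return data frame `date`, `anomaly` (deg C), with the smoothed
#'   day-of-year climatology in attribute `"climatology"`.
#' @export
seasonal_detrend <- function(series, smooth_window = 31) {
  col <- env_value_col(series)
  t <- series$date; v <- series[[col]]
  ok <- !is.na(v); t <- t[ok]; v <- v[ok]
  if (length(t) == 0 || diff(range(t)) < 2)
    stopf("seasonal detrending needs at least 2 full years of data")
  doy <- pmin(365L, floor((t %% 1) * 365.25) + 1L)
  clim_sum <- tapply(v, factor(doy, levels = 1:365), sum)
  clim_n <- tapply(rep(1, length(v)), factor(doy, levels = 1:365), sum)
  clim_sum[is.na(clim_sum)] <- 0; clim_n[is.na(clim_n)] <- 0
  # centred circular moving mean (triangular weights), NA-days borrow
  # from neighbours
  w <- max(1L, as.integer(smooth_window))
  half <- w %/% 2
  pad <- function(x) c(utils::tail(x, half), x, utils::head(x, half))
  ker <- half + 1 - abs(seq(-half, half))
  sm_sum <- stats::filter(pad(as.numeric(clim_sum)), ker, sides = 2)
  sm_n <- stats::filter(pad(as.numeric(clim_n)), ker, sides = 2)
  clim <- (sm_sum / sm_n)[(half + 1):(half + 365)]
  # evaluate the climatology continuously (circular linear interpolation
  # between day-of-year bin centres) to avoid binning quantization
  pos <- (t %% 1) * 365.25
  idx0 <- floor(pos - 0.5)
  wt <- pos - 0.5 - idx0
  i1 <- (idx0 %% 365) + 1
  i2 <- ((idx0 + 1) %% 365) + 1
  fitted <- (1 - wt) * clim[i1] + wt * clim[i2]
  out <- data.frame(date = t, anomaly = v - fitted)
  attr(out, "climatology") <- as.numeric(clim)
  attr(out, "fitted") <- fitted
  attr(out, "kind") <- "anomaly"
  out
}

#' Decimate a wave series to weekly maxima
#'
#' One record per calendar week: the maximum significant wave height in the
#' week and the wave period coincident with that maximum (earliest
#' observation wins on ties).
#'
#' @param series data frame with `date`, `hs` (m), `period` (s).
#' @return data frame `date` (week start, decimal years), `hs`, `period`.
#' @export
weekly_decimate <- function(series) {
  if (!all(c("hs", "period") %in% names(series)))
    stopf("weekly_decimate needs a wave series with columns hs, period")
  week <- floor(series$date * 365.25 / 7 + 1e-9)
  pick <- tapply(seq_len(nrow(series)), week, function(i) i[which.max(series$hs[i])])
  pick <- unname(unlist(pick))
  out <- data.frame(date = as.numeric(names(table(week))) * 7 / 365.25,
                    hs = series$hs[pick], period = series$period[pick])
  out[order(out$date), , drop = FALSE]
}

#' Deep-water wave energy density
#'
#' `E = rho * g * hs^2 / 16` in J m^-2. With the defaults
#' (`rho = 1025` kg m^-3, `g = 9.81` m s^-2), a 2-m significant wave height
#' gives 2513.8 J m^-2. Energy scales with the square of wave height; the
#' wave period does not enter the density.
#'
#' @param hs significant wave height (m), non-negative.
#' @param rho seawater density (kg m^-3).
#' @param g gravitational acceleration (m s^-2).
#' @return energy density (J m^-2).
#' @seealso [wave_energy_flux()] for the period-dependent energy flux.
#' @export
wave_energy <- function(hs, rho = 1025, g = 9.81) {
  if (any(hs < 0, na.rm = TRUE)) stopf("negative significant wave height")
  rho * g * hs^2 / 16
}

#' Deep-water wave energy flux
#'
#' `P = rho * g^2 * hs^2 * T / (64 * pi)` in W m^-1: an alternative,
#' period-dependent wave disturbance metric.
#'
#' @param hs significant wave height (m).
#' @param period wave period (s).
#' @inheritParams wave_energy
#' @return energy flux (W m^-1).
#' @export
wave_energy_flux <- function(hs, period, rho = 1025, g = 9.81) {
  if (any(hs < 0, na.rm = TRUE)) stopf("negative significant wave height")
  rho * g^2 * hs^2 * period / (64 * pi)
}

#' Weekly wave-energy series
#'
#' Convenience wrapper: weekly decimation followed by conversion of the
#' weekly maximum wave height to energy density.
#'
#' @inheritParams weekly_decimate
#' @inheritParams wave_energy
#' @param formula `"density"` (J m^-2, default) or `"flux"` (W m^-1).
#' @return data frame `date`, `hs`, `period`, `energy`.
#' @export
wave_energy_series <- function(series, rho = 1025, g = 9.81,
                               formula = c("density", "flux")) {
  formula <- match.arg(formula)
  wk <- weekly_decimate(series)
  wk$energy <- if (formula == "density") wave_energy(wk$hs, rho, g)
               else wave_energy_flux(wk$hs, wk$period, rho, g)
  attr(wk, "kind") <- "energy"
  wk
}

#' Empirical quantile of a series over a time window
#'
#' Linear interpolation between order statistics (type-7 quantile),
#' applied to observations with `t0 <= t < t1`.
#'
#' @param series data frame with `date` and one value column.
#' @param interval numeric `c(t0, t1)` in decimal years, `t0 < t1`.
#' @param q probability in \[0, 1\].
#' @return the quantile value.
#' @export
window_quantile <- function(series, interval, q) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  col <- env_value_col(series)
  inwin <- series$date >= interval[1] & series$date < interval[2]
  v <- series[[col]][inwin]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stopf("no observations in window [%.3f, %.3f)", interval[1], interval[2])
  unname(stats::quantile(v, probs = q, type = 7))
}
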