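# Cholesky factor of the autocovariance of fractional Gaussian noise with
# Hurst exponent H (unit marginal variance). Long-memory anomalies make the
# window-statistic scaling approximately log-log linear, which is the
# regime the scale extrapolation presumes.
fgn_chol <- function(n, hurst) {
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                abs(k - 1)^(2 * hurst))
  chol(stats::toeplitz(g))
}

#' Simulate a ground-truthed daily precipitation-isotope record
#'
#' Generates one synthetic site emulating the downscaler's input family:
#' wet-day occurrence by a two-state Markov chain, wet-day depths by a
#' gamma law, and daily d2H / d18O on wet days as a harmonic seasonal
#' cycle plus correlated zero-mean anomalies with prescribed
#' cross-correlation, correlation with precipitation amount, and
#' long-memory temporal persistence (fractional Gaussian noise). Biweekly
#' amount-weighted composites — the downscaler's exact input contract —
#' are derived from the daily truth.
#'
#' @param n_years Record length in years (default 3).
#' @param start_date First day (default 2019-01-01).
#' @param p_wet_given_dry,p_wet_given_wet Markov transition probabilities
#'   (defaults 0.45 / 0.65: stationary wet fraction 0.5625, a humid site).
#' @param depth_shape,depth_mean_mm Gamma shape and mean (mm) of wet-day
#'   depths (defaults 1.2 and 6).
#' @param sd_d2H,sd_d18O Daily anomaly standard deviations, permil
#'   (defaults 16 and 2).
#' @param rho_d2H_d18O Target daily correlation between the two tracers
#'   (default 0.95).
#' @param rho_d18O_P Target daily correlation between d18O and
#'   precipitation amount (default -0.3; d2H uses the same coupling, as on
#'   the meteoric water line).
#' @param amp_d2H,amp_d18O Seasonal amplitudes, permil (defaults 32 and 4).
#' @param mean_d2H,mean_d18O Long-term means, permil (defaults -70, -10).
#' @param phase Seasonal phase in radians (default -1.54: summer maximum).
#' @param hurst Hurst exponent of the anomaly persistence (default 0.85).
#' @param seed Integer seed; the fixture is a pure function of its
#'   arguments.
#' @return A list of class `"precip_truth"`:
#'   * `daily` — tibble `date, precip_mm, d2H, d18O, anom_d2H, anom_d18O`
#'     (isotope columns `NA` on dry days);
#'   * `composites` — tibble `window_start, window_end, precip_mm, d2H,
#'     d18O` over contiguous 14-day windows anchored at the record start
#'     (windows with zero precipitation are omitted; a trailing partial
#'     window is discarded);
#'   * `params` — every generator argument plus the realised wet-day
#'     anomaly sds and correlations.
#' @export
simulate_precip_site <- function(n_years = 3, start_date = as.Date("2019-01-01"),
                                 p_wet_given_dry = 0.45, p_wet_given_wet = 0.65,
                                 depth_shape = 1.2, depth_mean_mm = 6,
                                 sd_d2H = 16, sd_d18O = 2,
                                 rho_d2H_d18O = 0.95, rho_d18O_P = -0.3,
                                 amp_d2H = 32, amp_d18O = 4,
                                 mean_d2H = -70, mean_d18O = -10,
                                 phase = -1.54, hurst = 0.85, seed = 1) {
  stopifnot(p_wet_given_dry >= 0, p_wet_given_dry <= 1,
            p_wet_given_wet >= 0, p_wet_given_wet <= 1,
            depth_shape > 0, depth_mean_mm > 0, sd_d2H >= 0, sd_d18O >= 0,
            abs(rho_d2H_d18O) <= 1, abs(rho_d18O_P) <= 1,
            hurst > 0.5, hurst < 1)
  set.seed(seed)
  n <- round(n_years * 365)
  dates <- start_date + 0:(n - 1)
  t <- 0:(n - 1)

  # occurrence chain and depths
  p_stat <- p_wet_given_dry / (1 + p_wet_given_dry - p_wet_given_wet)
  wet <- logical(n)
  u <- stats::runif(n)
  wet[1] <- u[1] < p_stat
  for (i in 2:n) {
    wet[i] <- u[i] < if (wet[i - 1]) p_wet_given_wet else p_wet_given_dry
  }
  amount <- numeric(n)
  n_wet <- sum(wet)
  if (n_wet > 0) {
    amount[wet] <- stats::rgamma(n_wet, shape = depth_shape,
                                 scale = depth_mean_mm / depth_shape)
  }

  # anomalies: shared long-memory pair plus an amount-coupled component
  seas_d2H <- mean_d2H + amp_d2H * sin(2 * pi * t / 365.25 + phase)
  seas_d18O <- mean_d18O + amp_d18O * sin(2 * pi * t / 365.25 + phase)
  d2H <- rep(NA_real_, n); d18O <- rep(NA_real_, n)
  a2 <- rep(NA_real_, n); a8 <- rep(NA_real_, n)
  realised <- list(rho_d2H_d18O = NA_real_, rho_d18O_P = NA_real_,
                   sd_d2H = NA_real_, sd_d18O = NA_real_)
  if (n_wet > 0) {
    e8 <- e2 <- rep(0, n_wet)
    if (n_wet > 2 && sd_d18O > 0) {
      L <- fgn_chol(n, hurst)
      g1 <- as.vector(stats::rnorm(n) %*% L)
      g2 <- as.vector(stats::rnorm(n) %*% L)
      # standard-normal score of each wet-day amount (Weibull positions)
      zp <- stats::qnorm(rank(amount[wet]) / (n_wet + 1))
      c_zp <- stats::cor(zp, amount[wet])
      beta <- max(-0.9, min(0.9, rho_d18O_P / c_zp))
      r <- (rho_d2H_d18O - beta^2) / (1 - beta^2)
      r <- max(-1, min(1, r))
      g2 <- r * g1 + sqrt(1 - r^2) * g2
      e8 <- sqrt(1 - beta^2) * g1[wet] + beta * zp
      e2 <- sqrt(1 - beta^2) * g2[wet] + beta * zp
    }
    a8[wet] <- sd_d18O * e8
    a2[wet] <- sd_d2H * e2
    d18O[wet] <- seas_d18O[wet] + a8[wet]
    d2H[wet] <- seas_d2H[wet] + a2[wet]
    if (n_wet > 2 && sd_d18O > 0) {
      realised <- list(
        rho_d2H_d18O = stats::cor(a2[wet], a8[wet]),
        rho_d18O_P = stats::cor(a8[wet], amount[wet]),
        sd_d2H = stats::sd(a2[wet]),
        sd_d18O = stats::sd(a8[wet])
      )
    }
  }
  amount_full <- ifelse(wet, amount, 0)

  daily <- tibble::tibble(date = dates, precip_mm = amount_full,
                          d2H = d2H, d18O = d18O,
                          anom_d2H = a2, anom_d18O = a8)

  # biweekly amount-weighted composites
  n_win <- n %/% 14
  composites <- purrr::map_dfr(seq_len(n_win), function(b) {
    i <- ((b - 1) * 14 + 1):(b * 14)
    tot <- sum(amount_full[i])
    if (tot <= 0) return(NULL)
    tibble::tibble(
      window_start = dates[i[1]],
      window_end = dates[i[14]],
      precip_mm = tot,
      d2H = amount_weighted_mean(d2H[i], amount_full[i]),
      d18O = amount_weighted_mean(d18O[i], amount_full[i])
    )
  })

  structure(
    list(daily = daily, composites = composites,
         params = c(as.list(environment())[c(
           "n_years", "start_date", "p_wet_given_dry", "p_wet_given_wet",
           "depth_shape", "depth_mean_mm", "sd_d2H", "sd_d18O",
           "rho_d2H_d18O", "rho_d18O_P", "amp_d2H", "amp_d18O",
           "mean_d2H", "mean_d18O", "phase", "hurst", "seed")],
           list(realised = realised))),
    class = "precip_truth"
  )
}

#' @export
print.precip_truth <- function(x, ...) {
  cat("Synthetic precipitation-isotope site:", nrow(x$daily), "days,",
      sum(x$daily$precip_mm > 0), "wet,", nrow(x$composites),
      "biweekly composites\n")
  invisible(x)
}

# diurnal incoming shortwave curve: 0 at night, sinusoidal between 06:00
# and 18:00 with the given midday peak
diurnal_shortwave <- function(hour, peak = 800) {
  pmax(0, peak * sin(pi * (hour - 6) / 12))
}

#' Simulate a ground-truthed tower-profile record
#'
#' Emulates the mixing-model input family: multi-height observations of a
#' gas whose concentration and isotope ratio follow exact two-member
#' mixing between a background atmosphere and a surface source with a
#' slowly drifting isotope ratio, sampled hourly with a diurnal shortwave
#' curve. With `noise_delta = 0` the records satisfy the mass balance
#' exactly, so the Miller-Tans slope recovers the source ratio to
#' round-off.
#'
#' @param n_days Number of days (default 30).
#' @param start_date First day (default 2019-06-01).
#' @param n_heights Number of tower levels (default 4); lower levels see
#'   larger surface-flux enhancements.
#' @param obs_per_hour Observations per height per hour (default 1).
#' @param background_c Background mixing ratio (default 400, ppm CO2).
#' @param background_delta Background isotope ratio, permil (default -8.5).
#' @param source_delta_mean Mean source isotope ratio, permil
#'   (default -26).
#' @param source_delta_drift Amplitude of a slow sinusoidal drift of the
#'   daily source ratio across the record, permil (default 3).
#' @param excess_shape,excess_mean Gamma shape/mean of the surface-flux
#'   concentration enhancement at the lowest level (defaults 2 and 30).
#' @param noise_delta Iid Gaussian noise sd added to each measured delta,
#'   permil (default 0.15).
#' @param sw_peak Midday shortwave maximum, W m^-2 (default 800).
#' @param seed Integer seed.
#' @return A list of class `"tower_truth"`:
#'   * `records` — tibble `timestamp, height_id, mixing_ratio, delta,
#'     shortwave`;
#'   * `truth` — tibble `date, source_delta` (the per-day source ratio);
#'   * `params` — the generator arguments.
#' @export
simulate_tower_site <- function(n_days = 30, start_date = as.Date("2019-06-01"),
                                n_heights = 4, obs_per_hour = 1,
                                background_c = 400, background_delta = -8.5,
                                source_delta_mean = -26,
                                source_delta_drift = 3,
                                excess_shape = 2, excess_mean = 30,
                                noise_delta = 0.15, sw_peak = 800, seed = 1) {
  stopifnot(n_days >= 1, n_heights >= 1, background_c > 0,
            excess_shape > 0, excess_mean > 0, noise_delta >= 0)
  set.seed(seed)
  dates <- start_date + 0:(n_days - 1)
  src <- source_delta_mean +
    source_delta_drift * sin(2 * pi * seq_len(n_days) / max(n_days, 2))
  height_factor <- rev(seq_len(n_heights)) / n_heights # lowest level largest
  grid <- tidyr::expand_grid(
    day = seq_len(n_days),
    hour = 0:23,
    rep = seq_len(obs_per_hour),
    height = seq_len(n_heights)
  )
  excess <- stats::rgamma(nrow(grid), shape = excess_shape,
                          scale = excess_mean / excess_shape) *
    height_factor[grid$height]
  C <- background_c + excess
  delta <- (background_c * background_delta + excess * src[grid$day]) / C
  if (noise_delta > 0) delta <- delta + stats::rnorm(length(delta), 0, noise_delta)
  records <- tibble::tibble(
    timestamp = as.POSIXct(dates[grid$day], tz = "UTC") +
      grid$hour * 3600 + (grid$rep - 1) * 3600 / obs_per_hour,
    height_id = paste0("h", grid$height),
    mixing_ratio = C,
    delta = delta,
    shortwave = diurnal_shortwave(grid$hour, sw_peak)
  )
  structure(
    list(records = records,
         truth = tibble::tibble(date = dates, source_delta = src),
         params = as.list(environment())[c(
           "n_days", "start_date", "n_heights", "obs_per_hour",
           "background_c", "background_delta", "source_delta_mean",
           "source_delta_drift", "excess_shape", "excess_mean",
           "noise_delta", "sw_peak", "seed")]),
    class = "tower_truth"
  )
}

#' @export
print.tower_truth <- function(x, ...) {
  cat("Synthetic tower-profile record:", nrow(x$records), "observations over",
      nrow(x$truth), "days\n")
  invisible(x)
}
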