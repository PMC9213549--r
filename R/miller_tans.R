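#' Partition tower records into all-day / daytime / nighttime windows
#'
#' Duplicates each record into the `alltime` group and, when incoming
#' shortwave radiation is available, into `daytime` (shortwave at or above
#' the threshold) or `nighttime` (below it). Records without shortwave go
#' to `alltime` only.
#'
#' @param records A data frame of tower observations with at least a
#'   `shortwave` column (W m^-2, `NA` allowed).
#' @param sw_threshold Day/night threshold in W m^-2 (default 10, the
#'   standard eddy-covariance convention; the day side is inclusive).
#' @return A tibble with the input rows replicated and a `window` column
#'   in `{"alltime", "daytime", "nighttime"}`.
#' @export
partition_windows <- function(records, sw_threshold = 10) {
  stopifnot(is.data.frame(records))
  if (!"shortwave" %in% names(records)) {
    stop("records must have a shortwave column (NA allowed)", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  dplyr::bind_rows(
    dplyr::mutate(records, window = "alltime"),
    dplyr::mutate(dplyr::filter(records, .data$shortwave >= sw_threshold),
                  window = "daytime"),
    dplyr::mutate(dplyr::filter(records, .data$shortwave < sw_threshold),
                  window = "nighttime")
  )
}

#' Miller-Tans mixing-model regression
#'
#' Ordinary least squares of the product `mixing_ratio * delta` on
#' `mixing_ratio` (with intercept) over the observations pooled across
#' heights within one day x time-window. Under a two-member mixing model
#' the slope estimates the isotope ratio of the surface source/sink flux,
#' and its standard error is the published uncertainty.
#'
#' @param obs A data frame with columns `mixing_ratio` (gas concentration,
#'   any consistent unit, > 0) and `delta` (calibrated isotope ratio,
#'   permil).
#' @return A one-row tibble: `slope` (permil), `slope_se` (permil),
#'   `r_squared`, `n_obs`.
#' @details Requires `n >= 3` (slope, intercept and at least one residual
#'   degree of freedom); zero variance in the mixing ratio is a degenerate
#'   regression. Both conditions raise errors; [daily_flux_series()] maps
#'   them to an absent estimate (flag 1).
#' @examples
#' # exact two-member mixing: background 400 ppm at -8 permil,
#' # source at -26 permil
#' Cb <- 400; db <- -8; ds <- -26; C <- c(410, 420, 440, 480)
#' d <- (Cb * db + (C - Cb) * ds) / C
#' miller_tans_fit(data.frame(mixing_ratio = C, delta = d))
#' @export
miller_tans_fit <- function(obs) {
  stopifnot(is.data.frame(obs))
  x <- obs$mixing_ratio
  y <- obs$mixing_ratio * obs$delta
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient observations: n = ", n, " < 3", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate regression: zero variance in mixing ratio",
                     call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  s2 <- rss / (n - 2)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    slope_se = sqrt(s2 / sxx),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n_obs = n
  )
}

#' Keeling-plot regression
#'
#' The equivalent mass-balance formulation: OLS of `delta` on
#' `1 / mixing_ratio` with intercept; the intercept estimates the source
#' isotope ratio. Provided as an independent cross-check of
#' [miller_tans_fit()] — on exact two-member mixtures the Keeling
#' intercept and the Miller-Tans slope agree.
#'
#' @inheritParams miller_tans_fit
#' @return A one-row tibble: `intercept` (permil, the source estimate),
#'   `intercept_se`, `r_squared`, `n_obs`.
#' @export
keeling_fit <- function(obs) {
  stopifnot(is.data.frame(obs))
  x <- 1 / obs$mixing_ratio
  y <- obs$delta
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient observations: n = ", n, " < 3", call. = FALSE)
  if (sum((x - mean(x))^2) == 0) {
    stop("degenerate regression: zero variance in mixing ratio", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((x - mean(x))^2)
  s2 <- rss / (n - 2)
  tibble::tibble(
    intercept = unname(stats::coef(fit)[1]),
    intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n_obs = n
  )
}

#' Daily Miller-Tans flux-isotope series for one site and tracer
#'
#' Splits the records into the three shortwave time-windows, pools all
#' heights within each calendar date x window, fits the Miller-Tans
#' regression per group, and assigns quality flags per window series.
#' Dates inside the record span with no usable regression get an absent
#' estimate (`NA` slope, flag 1; serialised as -9999).
#'
#' @param records A data frame with columns `timestamp` (`POSIXct` or
#'   `Date`), `mixing_ratio`, `delta` and `shortwave`. A `height_id`
#'   column may be present but is not required: observations are pooled
#'   unweighted across heights.
#' @param sw_threshold Day/night shortwave threshold (W m^-2, default 10).
#' @param n_min,r2_min,iqr_k Flagging thresholds, see
#'   [flag_flux_estimates()].
#' @param dates Optional `Date` vector defining the output grid; defaults
#'   to the contiguous span of the record dates.
#' @return A tibble of class `"flux_series"` with one row per date x
#'   window: `date`, `window`, `slope`, `slope_se`, `r_squared`, `n_obs`,
#'   `flag`.
#' @export
daily_flux_series <- function(records, sw_threshold = 10, n_min = 5,
                              r2_min = 0.9, iqr_k = 1.5, dates = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("timestamp", "mixing_ratio", "delta")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records <- dplyr::mutate(tibble::as_tibble(records),
                           date = as.Date(.data$timestamp))
  if (is.null(dates)) {
    dates <- seq(min(records$date), max(records$date), by = "day")
  }
  grouped <- partition_windows(records, sw_threshold)
  fits <- dplyr::group_modify(
    dplyr::group_by(grouped, .data$date, .data$window),
    function(g, key) {
      tryCatch(miller_tans_fit(g), error = function(e) {
        tibble::tibble(slope = NA_real_, slope_se = NA_real_,
                       r_squared = NA_real_, n_obs = nrow(g))
      })
    }
  )
  grid <- tidyr::expand_grid(
    date = dates,
    window = c("alltime", "daytime", "nighttime")
  )
  full <- dplyr::left_join(grid, dplyr::ungroup(fits),
                           by = c("date", "window"))
  full$n_obs[is.na(full$n_obs)] <- 0L
  flagged <- dplyr::group_modify(
    dplyr::group_by(full, .data$window),
    function(g, key) flag_flux_estimates(g, n_min = n_min, r2_min = r2_min,
                                         iqr_k = iqr_k)
  )
  out <- dplyr::arrange(dplyr::ungroup(flagged), .data$window, .data$date)
  out <- dplyr::relocate(out, "date", "window")
  class(out) <- c("flux_series", class(out))
  out
}
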