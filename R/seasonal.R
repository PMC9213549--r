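#' Fit a harmonic seasonal cycle to an isotope time series
#'
#' Characterises the climatological seasonal cycle of a (typically biweekly)
#' isotope series as a sum of sinusoids,
#' \deqn{S(t) = c_0 + \sum_k A_k \sin(2\pi t/\tau_k + \phi_k),}
#' with \eqn{\tau_k = \code{base_period}/k}, fitted by least squares on the
#' linearised sine/cosine form.  The fitted residuals have mean zero by
#' construction, so the remainder of the series can be treated as a zero-mean
#' stochastic signal.
#'
#' @param data A data frame with one row per observation.
#' @param value Name of the column holding isotope ratios (permil).
#' @param date Name of the column holding dates (`Date`). Default `"date"`.
#' @param n_harmonics Number of harmonics. The default 2 fits the annual and
#'   semiannual cycles.
#' @param base_period Fundamental period in days (default 365.25); harmonic
#'   `k` has period `base_period / k`.
#' @param weights Optional name of a column of non-negative weights (e.g.
#'   precipitation amounts for an amount-weighted fit). Default unweighted.
#'
#' @return An object of class `"seasonal_model"`: a list with elements
#'   `mean_offset` (permil), `harmonics` (tibble with `k`, `period`,
#'   `amplitude`, `phase`), `reference_epoch` (the `Date` mapped to t = 0),
#'   `n_obs`, `sigma` (residual sd) and `r_squared`.
#'
#' @details Rows with a missing value or date are dropped from the fit, not
#'   imputed. At least `2 * n_harmonics + 1` non-missing observations are
#'   required. Amplitudes are non-negative and phases lie in `[-pi, pi]`.
#'
#' @examples
#' d <- tibble::tibble(
#'   date = as.Date("2019-01-01") + seq(0, 4 * 365, by = 14),
#'   d18O = -10 + 4 * sin(2 * pi * seq(0, 4 * 365, by = 14) / 365.25)
#' )
#' m <- fit_seasonal(d, "d18O")
#' tidy(m)
#' @export
fit_seasonal <- function(data, value, date = "date", n_harmonics = 2,
                         base_period = 365.25, weights = NULL) {
  stopifnot(is.data.frame(data), n_harmonics >= 1, base_period > 0)
  if (!value %in% names(data)) stop("column '", value, "' not found", call. = FALSE)
  if (!date %in% names(data)) stop("column '", date, "' not found", call. = FALSE)
  dates <- as.Date(data[[date]])
  y <- data[[value]]
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  keep <- !is.na(y) & !is.na(dates) & !is.na(w)
  dates <- dates[keep]; y <- y[keep]; w <- w[keep]
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (length(y) < 2 * n_harmonics + 1) {
    stop("too few observations: need at least ", 2 * n_harmonics + 1,
         " non-missing values to fit ", n_harmonics, " harmonics",
         call. = FALSE)
  }
  if (is.unsorted(as.numeric(dates), strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  epoch <- dates[1]
  t <- as.numeric(dates - epoch)
  X <- seasonal_design(t, n_harmonics, base_period)
  fit <- stats::lm.wfit(cbind(1, X), y, w)
  beta <- unname(fit$coefficients)
  harm <- purrr::map_dfr(seq_len(n_harmonics), function(k) {
    a <- beta[2 * k]       # sin coefficient
    b <- beta[2 * k + 1]   # cos coefficient
    tibble::tibble(
      k = k,
      period = base_period / k,
      amplitude = sqrt(a^2 + b^2),
      phase = atan2(b, a)
    )
  })
  res <- fit$residuals
  tss <- sum(w * (y - sum(w * y) / sum(w))^2)
  structure(
    list(
      mean_offset = unname(beta[1]),
      harmonics = harm,
      reference_epoch = epoch,
      base_period = base_period,
      n_obs = length(y),
      sigma = sqrt(sum(w * res^2) / max(1, length(y) - (2 * n_harmonics + 1))),
      r_squared = if (tss > 0) 1 - sum(w * res^2) / tss else NA_real_
    ),
    class = "seasonal_model"
  )
}

# sin/cos design matrix, columns ordered (sin_1, cos_1, sin_2, cos_2, ...)
seasonal_design <- function(t, n_harmonics, base_period) {
  cols <- lapply(seq_len(n_harmonics), function(k) {
    omega <- 2 * pi * k / base_period
    cbind(sin(omega * t), cos(omega * t))
  })
  do.call(cbind, cols)
}

#' Evaluate a fitted seasonal model at given dates
#'
#' @param object A `"seasonal_model"` from [fit_seasonal()].
#' @param dates A `Date` vector (or a data frame with a `date` column).
#' @param ... Unused.
#' @return Numeric vector of seasonal values (permil).
#' @export
predict.seasonal_model <- function(object, dates, ...) {
  if (is.data.frame(dates)) dates <- dates$date
  t <- as.numeric(as.Date(dates) - object$reference_epoch)
  out <- rep(object$mean_offset, length(t))
  for (i in seq_len(nrow(object$harmonics))) {
    h <- object$harmonics[i, ]
    out <- out + h$amplitude * sin(2 * pi * t / h$period + h$phase)
  }
  out
}

#' @export
print.seasonal_model <- function(x, ...) {
  cat("Seasonal harmonic model\n")
  cat("  mean offset:", format(x$mean_offset, digits = 5), "permil\n")
  cat("  epoch (t = 0):", format(x$reference_epoch), "\n")
  cat("  n =", x$n_obs, ", residual sd =", format(x$sigma, digits = 4), "\n")
  print(x$harmonics)
  invisible(x)
}

#' Remove a fitted seasonal cycle from a series
#'
#' Subtracts the seasonal model evaluated at each row's date, leaving the
#' zero-mean stochastic anomaly. Missing values propagate as missing.
#'
#' @inheritParams fit_seasonal
#' @param model A `"seasonal_model"` from [fit_seasonal()].
#' @return The input data as a tibble with two extra columns: `.seasonal`
#'   (the model evaluated at each date) and `.anomaly` (value minus
#'   seasonal).
#' @seealso [add_seasonal()] for the exact inverse.
#' @export
remove_seasonal <- function(data, model, value, date = "date") {
  stopifnot(inherits(model, "seasonal_model"))
  s <- predict(model, data[[date]])
  dplyr::mutate(tibble::as_tibble(data),
                .seasonal = s,
                .anomaly = .data[[value]] - s)
}

#' Add a fitted seasonal cycle back onto anomalies
#'
#' Exact inverse of [remove_seasonal()]: reconstructs values as
#' anomaly + seasonal.
#'
#' @inheritParams remove_seasonal
#' @param anomaly Name of the anomaly column (default `".anomaly"`).
#' @return The input data as a tibble with a `.value` column holding the
#'   reconstructed series.
#' @export
add_seasonal <- function(data, model, anomaly = ".anomaly", date = "date") {
  stopifnot(inherits(model, "seasonal_model"))
  s <- predict(model, data[[date]])
  dplyr::mutate(tibble::as_tibble(data), .value = .data[[anomaly]] + s)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a seasonal model
#'
#' @param x A `"seasonal_model"`.
#' @param ... Unused.
#' @return A tibble with one row per term (`mean_offset`, then one row per
#'   harmonic) and columns `term`, `period`, `amplitude`, `phase`.
#' @export
tidy.seasonal_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "mean_offset", period = NA_real_,
                   amplitude = x$mean_offset, phase = NA_real_),
    dplyr::transmute(x$harmonics,
                     term = paste0("harmonic_", .data$k),
                     period = .data$period,
                     amplitude = .data$amplitude,
                     phase = .data$phase)
  )
}

#' Glance at a seasonal model
#'
#' @param x A `"seasonal_model"`.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma`, `nobs`,
#'   `n_harmonics`, `base_period`.
#' @export
glance.seasonal_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    nobs = x$n_obs,
    n_harmonics = nrow(x$harmonics),
    base_period = x$base_period
  )
}
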