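#' Build the Gaussian copula linking precipitation amount and isotope anomalies
#'
#' Assembles the 3 x 3 correlation matrix over (P, d2H, d18O) from the
#' extrapolated daily target statistics, with normal margins for the two
#' isotope anomalies and an empirical margin (Weibull plotting positions,
#' linear interpolation) for positive daily precipitation amounts.
#'
#' @param daily_stats A `"daily_target_stats"` object from
#'   [extrapolate_to_daily()], or a one-row data frame with columns
#'   `mean_d2H`, `mean_d18O`, `sd_d2H`, `sd_d18O`, `rho_d2H_d18O`,
#'   `rho_d2H_P`, `rho_d18O_P`.
#' @param precip A data frame with a `precip_mm` column of daily amounts
#'   (or a bare numeric vector of amounts).
#' @param trace_mm Trace threshold (mm); only days with
#'   `precip_mm >= trace_mm` enter the empirical precipitation margin.
#' @return An object of class `"copula_spec"`: list with
#'   `correlation_matrix` (dimnames `P`, `d2H`, `d18O`), `margin_d2H`,
#'   `margin_d18O` (each `c(mean, sd)` in permil), `margin_P` (sorted wet-day
#'   amounts), `repaired` (logical) and `repair_delta` (max elementwise
#'   change if a positive-definiteness repair was applied).
#' @details A non-positive-definite matrix (possible when the three
#'   extrapolated correlations are mutually inconsistent) is repaired by
#'   flooring its eigenvalues at 1e-8 and renormalising to unit diagonal;
#'   if that moves any correlation by more than 0.05 the matrix is deemed
#'   unrepairable and the build fails.
#' @export
build_copula <- function(daily_stats, precip, trace_mm = 0.25) {
  st <- if (inherits(daily_stats, "daily_target_stats")) daily_stats$stats else daily_stats
  amounts <- if (is.data.frame(precip)) precip$precip_mm else precip
  wet <- sort(amounts[!is.na(amounts) & amounts >= trace_mm])
  if (length(wet) < 1) {
    stop("no precipitation days at or above the trace threshold", call. = FALSE)
  }
  R <- diag(3)
  dimnames(R) <- list(c("P", "d2H", "d18O"), c("P", "d2H", "d18O"))
  R["P", "d2H"] <- R["d2H", "P"] <- st$rho_d2H_P
  R["P", "d18O"] <- R["d18O", "P"] <- st$rho_d18O_P
  R["d2H", "d18O"] <- R["d18O", "d2H"] <- st$rho_d2H_d18O
  repaired <- FALSE
  repair_delta <- 0
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    # project towards the nearest correlation matrix: alternate eigenvalue
    # flooring with a unit-diagonal reset until positive definite
    R2 <- R
    for (it in 1:500) {
      e <- eigen(R2, symmetric = TRUE)
      R2 <- e$vectors %*% diag(pmax(e$values, 1e-8)) %*% t(e$vectors)
      diag(R2) <- 1
      if (min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) > 1e-10) break
    }
    R2 <- (R2 + t(R2)) / 2
    dimnames(R2) <- dimnames(R)
    repair_delta <- max(abs(R2 - R))
    if (repair_delta > 0.05 ||
        min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
      stop("correlation matrix unrepairable: positive-definiteness repair ",
           "moved a correlation by ", format(repair_delta, digits = 3),
           call. = FALSE)
    }
    R <- R2
    repaired <- TRUE
  }
  structure(
    list(
      correlation_matrix = R,
      margin_d2H = c(mean = unname(st$mean_d2H), sd = unname(st$sd_d2H)),
      margin_d18O = c(mean = unname(st$mean_d18O), sd = unname(st$sd_d18O)),
      margin_P = wet,
      trace_mm = trace_mm,
      repaired = repaired,
      repair_delta = repair_delta
    ),
    class = "copula_spec"
  )
}

#' @export
print.copula_spec <- function(x, ...) {
  cat("Gaussian copula over (P, d2H, d18O)\n")
  print(round(x$correlation_matrix, 4))
  cat("margins: d2H ~ N(", format(x$margin_d2H[1], digits = 4), ", ",
      format(x$margin_d2H[2], digits = 4), "^2), d18O ~ N(",
      format(x$margin_d18O[1], digits = 4), ", ",
      format(x$margin_d18O[2], digits = 4), "^2), P empirical on ",
      length(x$margin_P), " wet days\n", sep = "")
  if (x$repaired) cat("matrix repaired (max drift ",
                      format(x$repair_delta, digits = 3), ")\n", sep = "")
  invisible(x)
}

# Empirical CDF with Weibull plotting positions i/(n+1) and linear
# interpolation between order statistics; clamped to [1/(n+1), n/(n+1)] so
# the normal score is finite.
precip_to_uniform <- function(amount, sorted_wet) {
  n <- length(sorted_wet)
  p <- seq_len(n) / (n + 1)
  if (n == 1) return(rep(0.5, length(amount)))
  stats::approx(sorted_wet, p, xout = amount, rule = 2, ties = "ordered")$y
}

#' Sample daily isotope anomalies conditional on precipitation amount
#'
#' For each wet day, the precipitation amount is mapped to a uniform score
#' through its empirical margin and then to a standard normal score z1;
#' the isotope scores (z2, z3) are drawn from the conditional bivariate
#' normal given z1 (conditional mean `R21 z1`, covariance by Schur
#' complement) and mapped through the normal margins to permil anomalies.
#'
#' @param copula A `"copula_spec"` from [build_copula()].
#' @param precip_amount Numeric vector of daily amounts, all at or above
#'   the copula's trace threshold (filter first; a lower amount is a
#'   contract violation and errors).
#' @param seed Optional integer; when supplied the draw is deterministic.
#' @return A tibble with columns `d2H` and `d18O` (permil anomalies), one
#'   row per element of `precip_amount`.
#' @export
sample_conditional <- function(copula, precip_amount, seed = NULL) {
  stopifnot(inherits(copula, "copula_spec"))
  if (any(is.na(precip_amount)) || any(precip_amount < copula$trace_mm)) {
    stop("all amounts must be non-missing and >= the trace threshold (",
         copula$trace_mm, " mm); filter dry and trace days first",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(precip_amount)
  R <- copula$correlation_matrix
  z1 <- stats::qnorm(precip_to_uniform(precip_amount, copula$margin_P))
  R21 <- R[c("d2H", "d18O"), "P"]
  R22 <- R[c("d2H", "d18O"), c("d2H", "d18O")]
  cond_cov <- R22 - tcrossprod(R21) # Schur complement; R11 = 1
  L <- chol(cond_cov)
  eps <- matrix(stats::rnorm(2 * n), ncol = 2) %*% L
  z2 <- R21["d2H"] * z1 + eps[, 1]
  z3 <- R21["d18O"] * z1 + eps[, 2]
  tibble::tibble(
    d2H = copula$margin_d2H["mean"] + copula$margin_d2H["sd"] * z2,
    d18O = copula$margin_d18O["mean"] + copula$margin_d18O["sd"] * z3
  )
}

#' Force biweekly amount-weighted means of a daily member onto the
#' observed composites
#'
#' The residual correction: for each composite window, the difference
#' between the observed composite and the member's amount-weighted mean
#' over the window's wet days is added to every wet-day value in the
#' window, so the corrected member reproduces each observed biweekly
#' composite exactly.
#'
#' @param values Daily isotope values (permil) for one member, `NA` on
#'   dry/missing days.
#' @param precip Daily precipitation amounts (mm) on the same grid; days
#'   below `trace_mm` (or missing) carry zero weight.
#' @param dates `Date` vector on the same grid.
#' @param composites A data frame with columns `window_start`,
#'   `window_end` (inclusive dates) and a column named by `value_col`
#'   holding the observed composite (permil).
#' @param value_col Name of the composite column (e.g. `"d18O"`).
#' @param trace_mm Trace threshold (mm).
#' @return Numeric vector of corrected daily values. The attribute
#'   `"skipped_windows"` lists windows that had an observed composite but
#'   no wet day in the member (left uncorrected, with a warning).
#' @export
residual_correct <- function(values, precip, dates, composites,
                             value_col = "d18O", trace_mm = 0.25) {
  stopifnot(length(values) == length(precip), length(values) == length(dates))
  w <- ifelse(is.na(precip) | precip < trace_mm, 0, precip)
  skipped <- integer(0)
  for (i in seq_len(nrow(composites))) {
    obs <- composites[[value_col]][i]
    if (is.na(obs)) next
    in_win <- dates >= composites$window_start[i] &
      dates <= composites$window_end[i]
    wet <- in_win & w > 0 & !is.na(values)
    if (!any(wet)) { skipped <- c(skipped, i); next }
    delta <- obs - amount_weighted_mean(values[wet], w[wet])
    values[wet] <- values[wet] + delta
  }
  if (length(skipped) > 0) {
    warning(length(skipped), " composite window(s) had no wet days in the ",
            "member and were skipped", call. = FALSE)
  }
  attr(values, "skipped_windows") <- skipped
  values
}
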