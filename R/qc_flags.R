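#' Quality flag for a precipitation day
#'
#' Classifies each site-day for the downscaled precipitation-isotope
#' product: `0` = precipitation observed at or above the trace threshold
#' (a value is modelled), `1` = no precipitation data, `2` = observed
#' amount below the trace threshold. Flags 1 and 2 force the value cell to
#' the -9999 fill in the published files.
#'
#' @param amount Daily precipitation depth in mm; `NA` = no data.
#' @param trace_mm Trace threshold in mm (default 0.25). A day with
#'   `amount >= trace_mm` is downscalable; "trace" means strictly less.
#' @return Integer vector of flags in `{0, 1, 2}`.
#' @examples
#' flag_precip_day(c(NA, 0.1, 0.25, 3)) # 1 2 0 0
#' @export
flag_precip_day <- function(amount, trace_mm = 0.25) {
  stopifnot(trace_mm > 0)
  if (any(amount < 0, na.rm = TRUE)) {
    stop("negative precipitation amount", call. = FALSE)
  }
  dplyr::case_when(
    is.na(amount) ~ 1L,
    amount < trace_mm ~ 2L,
    TRUE ~ 0L
  )
}

#' Tukey fence bounds for the flux outlier flag
#'
#' Computes `[Q1 - k * IQR, Q3 + k * IQR]` over the qualifying flux series
#' with type-7 (linear interpolation) quantiles.
#'
#' @param values Numeric vector: the flux estimates that pass the sample
#'   size and R-squared criteria for one site x window x tracer series.
#' @param k Fence multiplier (default 1.5).
#' @return A named numeric vector `c(lower, upper)`, or `NULL` when fewer
#'   than 4 qualifying values exist (no IQR context; no outlier flag can be
#'   assigned).
#' @examples
#' compute_iqr_bounds(c(1, 2, 3, 4, 5, 100)) # -1.5, 8.5
#' @export
compute_iqr_bounds <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4) return(NULL)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Quality flags for a daily flux-isotope series
#'
#' Assigns the 0-4 flag scheme to one site x window x tracer series of
#' Miller-Tans estimates, with precedence `1 > 2 > 3 > 4 > 0`:
#'
#' * `1` — no estimate for the day (no calibrated observations, or a
#'   degenerate regression); the value cell is filled with -9999.
#' * `2` — low sample size, `n <= n_min`.
#' * `3` — regression `R^2 < r2_min`.
#' * `4` — slope beyond the Tukey fences `[Q1 - k IQR, Q3 + k IQR]` of the
#'   qualifying series (`n > n_min` and `R^2 >= r2_min`).
#' * `0` — a good estimate.
#'
#' Flag-2 and flag-3 estimates keep their numeric value; only flag 1 maps
#' to the fill value on disk. The `n = n_min` boundary is flagged 2
#' (conservative): the published rules give both "n <= 5 -> flag 2" and
#' "n >= 5 -> good", and precedence resolves the overlap in favour of
#' flagging.
#'
#' @param flux A data frame with columns `slope`, `r_squared`, `n_obs`
#'   (one row per day; `NA` slope = absent estimate).
#' @param n_min Minimum sample size (default 5); `n_obs <= n_min` flags 2.
#' @param r2_min Minimum R-squared (default 0.9).
#' @param iqr_k Tukey fence multiplier (default 1.5).
#' @return The input as a tibble with an integer `flag` column (and the
#'   attribute `"iqr_bounds"`, `NULL` when there was no IQR context).
#' @export
flag_flux_estimates <- function(flux, n_min = 5, r2_min = 0.9, iqr_k = 1.5) {
  stopifnot(is.data.frame(flux))
  need <- c("slope", "r_squared", "n_obs")
  if (!all(need %in% names(flux))) {
    stop("flux must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  qualifying <- !is.na(flux$slope) & flux$n_obs > n_min &
    !is.na(flux$r_squared) & flux$r_squared >= r2_min
  bounds <- compute_iqr_bounds(flux$slope[qualifying], k = iqr_k)
  out_of_fence <- if (is.null(bounds)) {
    rep(FALSE, nrow(flux))
  } else {
    !is.na(flux$slope) & (flux$slope < bounds["lower"] | flux$slope > bounds["upper"])
  }
  flag <- dplyr::case_when(
    is.na(flux$slope) ~ 1L,
    flux$n_obs <= n_min ~ 2L,
    is.na(flux$r_squared) | flux$r_squared < r2_min ~ 3L,
    out_of_fence ~ 4L,
    TRUE ~ 0L
  )
  out <- dplyr::mutate(tibble::as_tibble(flux), flag = flag)
  attr(out, "iqr_bounds") <- bounds
  out
}
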