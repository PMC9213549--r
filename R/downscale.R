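#' Downscale biweekly precipitation-isotope composites to a daily ensemble
#'
#' Runs the full statistical downscaling chain for one site:
#'
#' 1. flag each day (trace / missing precipitation, [flag_precip_day()]);
#' 2. fit and remove the harmonic seasonal cycle of the biweekly d2H and
#'    d18O composites ([fit_seasonal()]);
#' 3. aggregate the de-seasonalised composites across the scale ladder and
#'    extrapolate the means, standard deviations and Pearson correlations
#'    to daily resolution ([scale_statistics()], [extrapolate_to_daily()]);
#' 4. build a Gaussian copula over (P, d2H, d18O) and, for each ensemble
#'    member, sample daily anomalies conditioned on the observed daily
#'    precipitation amounts ([build_copula()], [sample_conditional()]);
#' 5. restore the seasonal cycle and apply the biweekly residual
#'    correction, forcing every member's biweekly amount-weighted means
#'    onto the observed composites ([residual_correct()]).
#'
#' Member `m` uses seed `base_seed + m`, so the ensemble is fully
#' deterministic given `base_seed`.
#'
#' @param precip A data frame with columns `date` (`Date`, one row per
#'   calendar day, contiguous) and `precip_mm` (daily depth, `NA` = no
#'   data).
#' @param composites A data frame with columns `window_start`,
#'   `window_end` (inclusive `Date`s of each biweekly collection window),
#'   `d2H` and `d18O` (observed composite ratios, permil). Windows with a
#'   missing composite are dropped from the fit, not imputed.
#' @param site Four-letter site code used in output files.
#' @param n_members Ensemble size (default 100).
#' @param trace_mm Trace precipitation threshold in mm (default 0.25);
#'   days below it are treated as dry.
#' @param base_seed Integer base seed (default 1).
#' @param n_harmonics,base_period Passed to [fit_seasonal()].
#' @param scales Aggregation ladder in days passed to [scale_statistics()].
#' @param fisher_z Passed to [extrapolate_to_daily()].
#' @param keep_members Keep the full member matrices (default `TRUE`).
#' @return An object of class `"precip_ensemble"`: a list with
#'   * `site`, `config`, `flags` — run metadata;
#'   * `summary` — tibble `date, precip_mm, flag, d2H_mean, d2H_sd,
#'     d18O_mean, d18O_sd` (`NA` isotope cells on dry/trace/missing days;
#'     written as -9999 on disk);
#'   * `members` — list of two `T x M` matrices (`d2H`, `d18O`) when
#'     `keep_members`;
#'   * `seasonal` — the two fitted seasonal models;
#'   * `ladder`, `daily_stats`, `copula` — intermediate statistics;
#'   * `skipped_windows` — composite windows with no wet day.
#' @examples
#' \donttest{
#' fx <- simulate_precip_site(n_years = 3, seed = 11)
#' ens <- downscale_precip(fx$daily, fx$composites, site = "SYNA",
#'                         n_members = 20, base_seed = 42)
#' glance(ens)
#' }
#' @export
downscale_precip <- function(precip, composites, site = "SITE",
                             n_members = 100, trace_mm = 0.25, base_seed = 1,
                             n_harmonics = 2, base_period = 365.25,
                             scales = c(14, 28, 42, 56, 70, 84),
                             fisher_z = FALSE, keep_members = TRUE) {
  stopifnot(is.data.frame(precip), is.data.frame(composites))
  if (!all(c("date", "precip_mm") %in% names(precip))) {
    stop("precip must have columns date, precip_mm", call. = FALSE)
  }
  if (!all(c("window_start", "window_end", "d2H", "d18O") %in% names(composites))) {
    stop("composites must have columns window_start, window_end, d2H, d18O",
         call. = FALSE)
  }
  precip <- dplyr::arrange(tibble::as_tibble(precip), .data$date)
  composites <- dplyr::arrange(tibble::as_tibble(composites), .data$window_start)

  flags <- flag_precip_day(precip$precip_mm, trace_mm)
  eff_p <- ifelse(flags == 0L, precip$precip_mm, 0) # trace/missing = dry
  wet <- eff_p >= trace_mm

  # -- seasonal cycle of the composites, dated at window midpoints
  comp <- dplyr::mutate(
    composites,
    date = .data$window_start + as.numeric(.data$window_end - .data$window_start) / 2,
    precip_mm = purrr::map2_dbl(.data$window_start, .data$window_end, function(a, b) {
      sum(eff_p[precip$date >= a & precip$date <= b])
    })
  )
  seas <- list(
    d2H = fit_seasonal(comp, "d2H", n_harmonics = n_harmonics,
                       base_period = base_period),
    d18O = fit_seasonal(comp, "d18O", n_harmonics = n_harmonics,
                        base_period = base_period)
  )
  anom <- dplyr::transmute(
    comp,
    window_start = .data$window_start,
    window_end = .data$window_end,
    d2H = .data$d2H - predict(seas$d2H, .data$date),
    d18O = .data$d18O - predict(seas$d18O, .data$date),
    # a window with a missing composite contributes no weight to coarser blocks
    precip_mm = ifelse(is.na(.data$d2H) | is.na(.data$d18O), 0, .data$precip_mm)
  )

  # -- scale ladder and daily target statistics
  ladder <- scale_statistics(anom, scales = scales, resolution = 14)
  daily_stats <- extrapolate_to_daily(ladder, fisher_z = fisher_z)

  # -- copula over (P, d2H, d18O)
  cop <- build_copula(daily_stats, eff_p, trace_mm = trace_mm)

  # windows with an observed composite but no wet day cannot be corrected
  has_wet <- purrr::map_lgl(seq_len(nrow(composites)), function(i) {
    any(wet & precip$date >= composites$window_start[i] &
          precip$date <= composites$window_end[i])
  })
  correctable <- composites[has_wet & !is.na(composites$d2H) &
                              !is.na(composites$d18O), ]
  skipped <- composites[has_wet == FALSE &
                          !(is.na(composites$d2H) | is.na(composites$d18O)), ]

  s_d2H <- predict(seas$d2H, precip$date)
  s_d18O <- predict(seas$d18O, precip$date)
  n_day <- nrow(precip)
  mem_d2H <- matrix(NA_real_, n_day, n_members)
  mem_d18O <- matrix(NA_real_, n_day, n_members)
  for (m in seq_len(n_members)) {
    set.seed(base_seed + m)
    draw <- sample_conditional(cop, eff_p[wet])
    v2 <- rep(NA_real_, n_day); v8 <- rep(NA_real_, n_day)
    v2[wet] <- draw$d2H + s_d2H[wet]
    v8[wet] <- draw$d18O + s_d18O[wet]
    v2 <- residual_correct(v2, eff_p, precip$date, correctable,
                           value_col = "d2H", trace_mm = trace_mm)
    v8 <- residual_correct(v8, eff_p, precip$date, correctable,
                           value_col = "d18O", trace_mm = trace_mm)
    mem_d2H[, m] <- v2
    mem_d18O[, m] <- v8
  }

  row_sd <- function(mat) {
    if (ncol(mat) == 1) return(ifelse(is.na(mat[, 1]), NA_real_, 0))
    apply(mat, 1, stats::sd)
  }
  summary <- tibble::tibble(
    date = precip$date,
    precip_mm = precip$precip_mm,
    flag = flags,
    d2H_mean = rowMeans(mem_d2H),
    d2H_sd = row_sd(mem_d2H),
    d18O_mean = rowMeans(mem_d18O),
    d18O_sd = row_sd(mem_d18O)
  )

  structure(
    list(
      site = site,
      summary = summary,
      members = if (keep_members) list(d2H = mem_d2H, d18O = mem_d18O),
      member_seed = base_seed + seq_len(n_members),
      seasonal = seas,
      ladder = ladder,
      daily_stats = daily_stats,
      copula = cop,
      skipped_windows = skipped,
      composites = composites,
      config = list(n_members = n_members, trace_mm = trace_mm,
                    base_seed = base_seed, n_harmonics = n_harmonics,
                    base_period = base_period, scales = scales,
                    fisher_z = fisher_z)
    ),
    class = "precip_ensemble"
  )
}

#' @export
print.precip_ensemble <- function(x, ...) {
  cat("Downscaled daily precipitation-isotope ensemble for site", x$site, "\n")
  cat("  ", nrow(x$summary), "days,", x$config$n_members, "members,",
      sum(x$summary$flag == 0L), "wet days\n")
  cat("  daily target sd: d2H", format(x$daily_stats$stats$sd_d2H, digits = 4),
      "permil, d18O", format(x$daily_stats$stats$sd_d18O, digits = 4),
      "permil\n")
  invisible(x)
}

#' Tidy a downscaled ensemble
#'
#' @param x A `"precip_ensemble"`.
#' @param ... Unused.
#' @return A long tibble with columns `site`, `date`, `precip_mm`, `flag`,
#'   `tracer` (`"d2H"`/`"d18O"`), `mean`, `sd`.
#' @export
tidy.precip_ensemble <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$summary,
    cols = c("d2H_mean", "d2H_sd", "d18O_mean", "d18O_sd"),
    names_to = c("tracer", ".value"),
    names_pattern = "(d2H|d18O)_(mean|sd)"
  )
  dplyr::mutate(long, site = x$site, .before = 1)
}

#' Glance at a downscaled ensemble
#'
#' @param x A `"precip_ensemble"`.
#' @param ... Unused.
#' @return A one-row tibble: site, days, wet days, members, the mean
#'   per-day ensemble sd of each tracer, and the extrapolated daily target
#'   sds.
#' @export
glance.precip_ensemble <- function(x, ...) {
  wet <- x$summary$flag == 0L
  tibble::tibble(
    site = x$site,
    n_days = nrow(x$summary),
    n_wet_days = sum(wet),
    n_members = x$config$n_members,
    mean_ensemble_sd_d2H = mean(x$summary$d2H_sd[wet], na.rm = TRUE),
    mean_ensemble_sd_d18O = mean(x$summary$d18O_sd[wet], na.rm = TRUE),
    target_sd_d2H = x$daily_stats$stats$sd_d2H,
    target_sd_d18O = x$daily_stats$stats$sd_d18O,
    n_skipped_windows = nrow(x$skipped_windows)
  )
}
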