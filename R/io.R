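# 6 significant digits on disk; full precision is kept in memory.
format_cell <- function(x) signif(x, 6)

# wide date x site tibble from a long (date, site, value) tibble, with the
# sentinel written into missing cells
widen <- function(long, dates, sites, fill = -9999) {
  grid <- tidyr::expand_grid(date = dates, site = sites)
  wide <- tidyr::pivot_wider(
    dplyr::left_join(grid, long, by = c("date", "site")),
    names_from = "site", values_from = "value"
  )
  wide[is.na(wide)] <- fill
  wide
}

#' Write the daily precipitation-isotope file set
#'
#' Serialises one or more downscaled ensembles to the published wide-matrix
#' layout: `daily_p_d2H_mean.csv`, `daily_p_d2H_std.csv`,
#' `daily_p_d18O_mean.csv`, `daily_p_d18O_std.csv` and
#' `daily_p_metadata.csv`. Rows are contiguous ISO-8601 calendar dates
#' spanning all sites; columns are site codes. Cells on days with flag 1
#' (no data) or 2 (trace) are the literal `-9999` fill; metadata flags are
#' integers. Values are written with 6 significant digits.
#'
#' @param results A `"precip_ensemble"` or a list of them (one per site).
#' @param outdir Output directory (created if needed).
#' @param members Also write every ensemble member under
#'   `ensemble_members/` (`daily_p_<tracer>_member_<mmm>.csv`). Default
#'   `FALSE`.
#' @return Invisibly, the paths written.
#' @export
write_precip_outputs <- function(results, outdir, members = FALSE) {
  if (inherits(results, "precip_ensemble")) results <- list(results)
  stopifnot(all(purrr::map_lgl(results, inherits, "precip_ensemble")))
  sites <- purrr::map_chr(results, "site")
  if (anyDuplicated(sites)) stop("duplicate site codes", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_dates <- purrr::map(results, function(r) r$summary$date)
  dates <- seq(min(as.Date(unlist(all_dates), origin = "1970-01-01")),
               max(as.Date(unlist(all_dates), origin = "1970-01-01")),
               by = "day")

  long_of <- function(col) {
    purrr::map2_dfr(results, sites, function(r, s) {
      tibble::tibble(date = r$summary$date, site = s,
                     value = format_cell(r$summary[[col]]))
    })
  }
  paths <- character(0)
  specs <- list(
    daily_p_d2H_mean.csv = "d2H_mean", daily_p_d2H_std.csv = "d2H_sd",
    daily_p_d18O_mean.csv = "d18O_mean", daily_p_d18O_std.csv = "d18O_sd"
  )
  for (fn in names(specs)) {
    path <- file.path(outdir, fn)
    readr::write_csv(widen(long_of(specs[[fn]]), dates, sites), path)
    paths <- c(paths, path)
  }
  meta_long <- purrr::map2_dfr(results, sites, function(r, s) {
    tibble::tibble(date = r$summary$date, site = s,
                   value = as.integer(r$summary$flag))
  })
  meta <- widen(meta_long, dates, sites, fill = 1L) # no record = no data
  path <- file.path(outdir, "daily_p_metadata.csv")
  readr::write_csv(meta, path)
  paths <- c(paths, path)

  if (members) {
    mdir <- file.path(outdir, "ensemble_members")
    dir.create(mdir, showWarnings = FALSE)
    n_m <- max(purrr::map_int(results, function(r) ncol(r$members$d2H)))
    for (tr in c("d2H", "d18O")) {
      for (m in seq_len(n_m)) {
        long <- purrr::map2_dfr(results, sites, function(r, s) {
          v <- if (m <= ncol(r$members[[tr]])) r$members[[tr]][, m]
               else rep(NA_real_, nrow(r$summary))
          tibble::tibble(date = r$summary$date, site = s,
                         value = format_cell(v))
        })
        path <- file.path(mdir, sprintf("daily_p_%s_member_%03d.csv", tr, m))
        readr::write_csv(widen(long, dates, sites), path)
        paths <- c(paths, path)
      }
    }
  }
  invisible(paths)
}

# file stem for a tracer: water tracers are ET, carbon is NEE
gas_stem <- function(tracer) {
  switch(tracer,
         d2H = "daily_et_flux_d2H",
         d18O = "daily_et_flux_d18O",
         d13C = "daily_nee_flux_d13C",
         stop("unknown tracer '", tracer, "'", call. = FALSE))
}

#' Write the daily flux-isotope file set
#'
#' Serialises daily Miller-Tans estimates to the published layout: per
#' tracer x time-window a value file (`daily_et_flux_d2H_alltime.csv`,
#' ..., `daily_nee_flux_d13C_nighttime.csv`), an `_error` file holding the
#' standard error of the regression slope, and a `_metadata` file of
#' integer quality flags — 27 files for the default three tracers and
#' three windows. Flag-1 cells (no estimate) are the `-9999` fill in both
#' the value and error files; flag-2/3/4 estimates keep their numeric
#' value.
#'
#' @param flux A data frame with columns `site`, `date`, `window`,
#'   `tracer` (`"d2H"`, `"d18O"`, `"d13C"`), `slope`, `slope_se`, `flag`.
#' @param outdir Output directory (created if needed).
#' @param tracers,windows The tracer x window inventory to emit (defaults
#'   cover the full published set; combinations absent from `flux` are
#'   written as all-fill with flag 1).
#' @return Invisibly, the paths written.
#' @export
write_gas_outputs <- function(flux, outdir,
                              tracers = c("d2H", "d18O", "d13C"),
                              windows = c("alltime", "daytime", "nighttime")) {
  stopifnot(is.data.frame(flux))
  need <- c("site", "date", "window", "tracer", "slope", "slope_se", "flag")
  if (!all(need %in% names(flux))) {
    stop("flux must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dates <- seq(min(flux$date), max(flux$date), by = "day")
  sites <- sort(unique(flux$site))
  paths <- character(0)
  for (tr in tracers) {
    for (win in windows) {
      sub <- dplyr::filter(flux, .data$tracer == tr, .data$window == win)
      val <- dplyr::transmute(sub, date = .data$date, site = .data$site,
                              value = ifelse(.data$flag == 1L, NA_real_,
                                             format_cell(.data$slope)))
      err <- dplyr::transmute(sub, date = .data$date, site = .data$site,
                              value = ifelse(.data$flag == 1L, NA_real_,
                                             format_cell(.data$slope_se)))
      meta <- dplyr::transmute(sub, date = .data$date, site = .data$site,
                               value = as.integer(.data$flag))
      stem <- file.path(outdir, paste0(gas_stem(tr), "_", win))
      readr::write_csv(widen(val, dates, sites), paste0(stem, ".csv"))
      readr::write_csv(widen(err, dates, sites), paste0(stem, "_error.csv"))
      readr::write_csv(widen(meta, dates, sites, fill = 1L),
                       paste0(stem, "_metadata.csv"))
      paths <- c(paths, paste0(stem, c(".csv", "_error.csv", "_metadata.csv")))
    }
  }
  invisible(paths)
}

#' Read a wide date x site matrix file
#'
#' @param path A CSV written by [write_precip_outputs()] or
#'   [write_gas_outputs()].
#' @param sentinel_to_na Convert `-9999` fill cells to `NA` (default
#'   `FALSE`: the matrix round-trips literally).
#' @return A tibble with a `date` column and one numeric column per site.
#' @export
read_wide_matrix <- function(path, sentinel_to_na = FALSE) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(date = readr::col_date()))
  if (sentinel_to_na) {
    out <- dplyr::mutate(out, dplyr::across(-"date",
                                            function(x) ifelse(x == -9999, NA, x)))
  }
  out
}

#' Daily flux-isotope estimates for a set of tower records
#'
#' Convenience wrapper running [daily_flux_series()] per tracer (and site)
#' and stacking the results into the long table [write_gas_outputs()]
#' consumes.
#'
#' @param records A data frame with columns `timestamp`, `mixing_ratio`,
#'   `delta`, `shortwave`, `tracer` and optionally `site` (default
#'   `"SITE"`).
#' @inheritParams daily_flux_series
#' @return A tibble of class `"flux_iso"` with columns `site`, `date`,
#'   `window`, `tracer`, `slope`, `slope_se`, `r_squared`, `n_obs`,
#'   `flag`.
#' @export
estimate_flux_iso <- function(records, sw_threshold = 10, n_min = 5,
                              r2_min = 0.9, iqr_k = 1.5, dates = NULL) {
  stopifnot(is.data.frame(records))
  if (!"tracer" %in% names(records)) {
    stop("records must have a tracer column", call. = FALSE)
  }
  if (!"site" %in% names(records)) records$site <- "SITE"
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(records), .data$site, .data$tracer),
    function(g, key) {
      daily_flux_series(g, sw_threshold = sw_threshold, n_min = n_min,
                        r2_min = r2_min, iqr_k = iqr_k, dates = dates)
    }
  )
  out <- dplyr::relocate(dplyr::ungroup(out), "site", "date", "window",
                         "tracer")
  class(out) <- c("flux_iso", class(out))
  out
}
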