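# Exact two-member mixing records: background (Cb, db) plus a source at ds.
# delta follows the mass balance exactly, so the Miller-Tans slope is ds.
two_member_mix <- function(C, Cb = 400, db = -8, ds = -26) {
  tibble::tibble(
    mixing_ratio = C,
    delta = (Cb * db + (C - Cb) * ds) / C
  )
}

# Independent OLS oracle via the normal equations (no lm anywhere):
# slope, SE(slope) and R-squared of y ~ 1 + x.
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n; ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  b <- sxy / sxx
  a <- ybar - b * xbar
  res <- y - a - b * x
  rss <- sum(res^2)
  tss <- sum((y - ybar)^2)
  list(slope = b, slope_se = sqrt(rss / (n - 2) / sxx),
       r_squared = 1 - rss / tss)
}

# Biweekly anomaly fixture with exactly known per-window values
biweekly_fixture <- function(n_windows = 24, seed = 7) {
  set.seed(seed)
  tibble::tibble(
    d2H = stats::rnorm(n_windows, 0, 8),
    d18O = stats::rnorm(n_windows, 0, 1),
    precip_mm = stats::rgamma(n_windows, 2, scale = 20)
  )
}

# A 3-year synthetic site shared across the slower tests
shared_precip_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_precip_site(n_years = 3, seed = 101)
    cache
  }
})

# A small downscaled ensemble shared across the downscale/io tests
small_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- shared_precip_fixture()
      cache <<- downscale_precip(fx$daily, fx$composites, site = "SYNA",
                                 n_members = 8, base_seed = 7)
    }
    cache
  }
})

# Run the installed command-line interface; returns list(status, stdout)
run_cli <- function(args) {
  cli <- system.file("exec", "fluxiso", package = "fluxiso")
  if (cli == "") cli <- file.path(find.package("fluxiso"), "exec", "fluxiso")
  out <- suppressWarnings(system2(
    "Rscript", c(cli, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
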