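test_that("amount_weighted_mean computes the composite kernel", {
  expect_equal(amount_weighted_mean(c(-10, -4), c(10, 5)), -8)
  expect_equal(amount_weighted_mean(c(-3, -7, -11), rep(2, 3)), mean(c(-3, -7, -11)))
  expect_equal(amount_weighted_mean(c(-3, -7, -11), c(0, 4, 0)), -7)
  # a zero-weight member may be missing, a weighted one may not
  expect_equal(amount_weighted_mean(c(NA, -4), c(0, 5)), -4)
  expect_error(amount_weighted_mean(c(NA, -4), c(1, 5)), "missing value")
  expect_error(amount_weighted_mean(c(-10, -4), c(0, 0)), "empty composite")
  expect_error(amount_weighted_mean(c(-10, -4), c(-1, 5)), "non-negative")
  expect_error(amount_weighted_mean(c(-10), c(1, 2)), "equal length")
})

test_that("aggregation preserves constants and perfect correlation", {
  d <- tibble::tibble(d2H = -8, d18O = -8, precip_mm = rgamma(24, 2, 0.1))
  for (s in c(14, 28, 42)) {
    a <- aggregate_series(d, s)
    expect_equal(a$mean_d2H, -8)
    expect_equal(a$sd_d2H, 0)
  }
  set.seed(1)
  d2 <- tibble::tibble(d2H = rnorm(24), precip_mm = rgamma(24, 2, 0.1))
  d2$d18O <- d2$d2H # identical tracers
  for (s in c(14, 28, 84)) {
    expect_equal(aggregate_series(d2, s)$rho_d2H_d18O, 1, tolerance = 1e-12)
  }
})

test_that("window statistics match a brute-force recomputation oracle", {
  d <- biweekly_fixture(n_windows = 25)
  for (s in c(14, 28, 56)) {
    k <- s / 14
    nb <- nrow(d) %/% k
    # oracle: plain loops, no package code
    P <- v2 <- v8 <- numeric(nb)
    for (b in seq_len(nb)) {
      i <- ((b - 1) * k + 1):(b * k)
      P[b] <- sum(d$precip_mm[i])
      v2[b] <- sum(d$d2H[i] * d$precip_mm[i]) / P[b]
      v8[b] <- sum(d$d18O[i] * d$precip_mm[i]) / P[b]
    }
    a <- aggregate_series(d, s)
    expect_equal(a$n_windows, nb)
    expect_equal(a$mean_d2H, mean(v2), tolerance = 1e-10)
    expect_equal(a$sd_d18O, sd(v8), tolerance = 1e-10)
    expect_equal(a$rho_d2H_d18O, cor(v2, v8), tolerance = 1e-10)
    expect_equal(a$rho_d2H_P, cor(v2, P), tolerance = 1e-10)
    expect_equal(a$rho_d18O_P, cor(v8, P), tolerance = 1e-10)
  }
})

test_that("aggregation at the input resolution reproduces the input statistics", {
  d <- biweekly_fixture()
  a <- aggregate_series(d, 14)
  expect_equal(a$mean_d2H, mean(d$d2H), tolerance = 1e-12)
  expect_equal(a$sd_d2H, sd(d$d2H), tolerance = 1e-12)
  expect_equal(a$rho_d18O_P, cor(d$d18O, d$precip_mm), tolerance = 1e-12)
})

test_that("zero-precipitation blocks are excluded and scarcity errors", {
  d <- biweekly_fixture(n_windows = 12)
  d$precip_mm[5:6] <- 0
  d$d2H[5:6] <- NA
  d$d18O[5:6] <- NA
  a <- aggregate_series(d, 14)
  expect_equal(a$n_windows, 10)
  expect_error(aggregate_series(d[1:5, ], 28), "insufficient windows")
  expect_error(aggregate_series(d, 15), "integer multiple")
})

test_that("flat statistics extrapolate to the constant", {
  st <- tibble::tibble(
    scale = c(14, 28, 42, 56, 70, 84), n_windows = 20,
    mean_d2H = -1, mean_d18O = -0.2, sd_d2H = 8, sd_d18O = 1,
    rho_d2H_d18O = 0.9, rho_d2H_P = -0.2, rho_d18O_P = -0.3
  )
  out <- extrapolate_to_daily(st)
  expect_equal(out$stats$sd_d2H, 8, tolerance = 1e-9)
  expect_equal(out$stats$rho_d2H_d18O, 0.9, tolerance = 1e-9)
  # de-seasonalised means are pinned at zero, trend kept as diagnostic
  expect_equal(out$stats$mean_d2H, 0)
  expect_equal(
    out$provenance$intercept[out$provenance$statistic == "mean_d2H"], -1,
    tolerance = 1e-9
  )
})

test_that("a power-law sd trend extrapolates to its daily coefficient", {
  sigma1 <- c(d2H = 11.3, d18O = 1.7)
  taus <- c(14, 28, 42, 56, 70, 84)
  st <- tibble::tibble(
    scale = taus, n_windows = 20,
    mean_d2H = 0, mean_d18O = 0,
    sd_d2H = sigma1["d2H"] * taus^(1 / 2),
    sd_d18O = sigma1["d18O"] * taus^(1 / 2),
    rho_d2H_d18O = 0.9, rho_d2H_P = -0.2, rho_d18O_P = -0.3
  )
  out <- extrapolate_to_daily(st)
  expect_equal(out$stats$sd_d2H, unname(sigma1["d2H"]), tolerance = 1e-6)
  expect_equal(out$stats$sd_d18O, unname(sigma1["d18O"]), tolerance = 1e-6)
})

test_that("correlation trends crossing 1 are clipped and recorded", {
  taus <- c(14, 28, 42, 56, 70, 84)
  st <- tibble::tibble(
    scale = taus, n_windows = 20, mean_d2H = 0, mean_d18O = 0,
    sd_d2H = 8, sd_d18O = 1,
    rho_d2H_d18O = pmin(1.2 - 0.1 * log(taus), 0.999), # rises past 1 at tau = 1
    rho_d2H_P = -0.2, rho_d18O_P = -0.3
  )
  out <- extrapolate_to_daily(st)
  expect_equal(out$stats$rho_d2H_d18O, 0.999)
  expect_equal(
    out$provenance$adjusted[out$provenance$statistic == "rho_d2H_d18O"],
    "clipped"
  )
  expect_error(extrapolate_to_daily(st[1:2, ]), "at least 3")
  st_bad <- st; st_bad$scale <- 14
  expect_error(extrapolate_to_daily(st_bad), "3 distinct|identical")
})
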