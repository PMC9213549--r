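stats_row <- function(rho_HO = 0.95, rho_2P = -0.3, rho_8P = -0.3,
                      sd2 = 16, sd8 = 2) {
  tibble::tibble(scale = 1, mean_d2H = 0, mean_d18O = 0,
                 sd_d2H = sd2, sd_d18O = sd8,
                 rho_d2H_d18O = rho_HO, rho_d2H_P = rho_2P,
                 rho_d18O_P = rho_8P)
}

test_that("uncorrelated targets give the identity matrix with no repair", {
  cop <- build_copula(stats_row(0, 0, 0), rgamma(50, 2, 0.5) + 0.25)
  expect_equal(unname(cop$correlation_matrix), diag(3))
  expect_false(cop$repaired)
})

test_that("a consistent correlation triple is positive definite", {
  cop <- build_copula(stats_row(0.95, -0.3, -0.3), rgamma(50, 2, 0.5) + 0.25)
  ev <- eigen(cop$correlation_matrix, symmetric = TRUE, only.values = TRUE)
  expect_true(all(ev$values > 1e-10))
  expect_gt(det(cop$correlation_matrix), 0)
  expect_false(cop$repaired)
})

test_that("an inconsistent triple fails rather than silently drifting", {
  # rho(d2H,d18O) = 0.9 with P-correlations +0.9 / -0.9 is far from any
  # valid correlation matrix; the bounded repair must refuse it
  expect_error(
    build_copula(stats_row(0.9, 0.9, -0.9), rgamma(50, 2, 0.5) + 0.25),
    "unrepairable"
  )
})

test_that("a mildly inconsistent triple is repaired close to the projection oracle", {
  # barely indefinite: rho(d2H,d18O) ~ 1, both P-correlations moderate
  st <- stats_row(0.999, -0.5, -0.42)
  R0 <- matrix(c(1, -0.5, -0.42, -0.5, 1, 0.999, -0.42, 0.999, 1), 3)
  expect_lt(min(eigen(R0, symmetric = TRUE)$values), 0)
  cop <- build_copula(st, rgamma(50, 2, 0.5) + 0.25)
  expect_true(cop$repaired)
  ev <- eigen(cop$correlation_matrix, symmetric = TRUE, only.values = TRUE)
  expect_true(all(ev$values > 0))
  # projection oracle: alternating eigenvalue floor + unit-diagonal reset
  P <- R0
  for (i in 1:500) {
    e <- eigen(P, symmetric = TRUE)
    P <- e$vectors %*% diag(pmax(e$values, 1e-8)) %*% t(e$vectors)
    diag(P) <- 1
  }
  expect_lt(max(abs(unname(cop$correlation_matrix) - P)), 0.05)
})

test_that("conditional sampling reduces to the margin under independence", {
  cop <- build_copula(stats_row(0, 0, 0), rgamma(200, 2, 0.5) + 0.25)
  set.seed(5)
  n <- 1e5
  draw <- sample_conditional(cop, rep(c(1, 5, 20), length.out = n))
  se_mean <- 2 / sqrt(n)
  expect_lt(abs(mean(draw$d18O) - 0), 3 * se_mean)
  se_sd <- 2 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(draw$d18O) - 2), 3 * se_sd)
})

test_that("the sampled cross-correlation matches the copula", {
  cop <- build_copula(stats_row(0.95, 0, 0), rgamma(200, 2, 0.5) + 0.25)
  set.seed(6)
  draw <- sample_conditional(cop, rgamma(1e5, 2, 0.5) + 0.25)
  expect_lt(abs(cor(draw$d2H, draw$d18O) - 0.95), 0.02)
})

test_that("conditional Gaussian scores follow N(rho z1, 1 - rho^2)", {
  rho <- 0.6
  amounts <- sort(rgamma(999, 2, 0.5)) + 0.25
  cop <- build_copula(stats_row(0.3, rho, 0), amounts)
  # condition on one fixed amount -> fixed z1 (Weibull position of the median)
  a_star <- amounts[500]
  z1 <- qnorm(500 / 1000)
  set.seed(7)
  n <- 1e5
  draw <- sample_conditional(cop, rep(a_star, n))
  z2 <- (draw$d2H - 0) / 16
  expect_lt(abs(mean(z2) - rho * z1), 3 * sd(z2) / sqrt(n))
  v <- 1 - rho^2
  se_var <- v * sqrt(2 / (n - 1))
  expect_lt(abs(var(z2) - v), 3 * se_var)
})

test_that("sampling is deterministic given a seed", {
  cop <- build_copula(stats_row(), rgamma(50, 2, 0.5) + 0.25)
  d1 <- sample_conditional(cop, c(1, 3, 7), seed = 99)
  d2 <- sample_conditional(cop, c(1, 3, 7), seed = 99)
  expect_identical(d1, d2)
  expect_error(sample_conditional(cop, c(0.1, 3)), "trace threshold")
})

test_that("residual correction forces biweekly means onto the composites", {
  dates <- as.Date("2019-01-01") + 0:27
  comps <- tibble::tibble(
    window_start = as.Date(c("2019-01-01", "2019-01-15")),
    window_end = as.Date(c("2019-01-14", "2019-01-28")),
    d18O = c(-9, -12)
  )
  # window already matching -> unchanged
  p <- c(10, 5, rep(0, 12), 8, rep(0, 13))
  v <- c(-10, -7, rep(NA, 12), -12, rep(NA, 13))
  # window 1 weighted mean = (10*-10 + 5*-7)/15 = -9 -> delta 0
  out <- residual_correct(v, p, dates, comps, "d18O")
  expect_equal(out[1:2], v[1:2])
  expect_equal(out[15], -12)
  # worked arithmetic: member [-10, -4], P [10, 5], observed -9 -> shift -1
  p2 <- c(10, 5, rep(0, 26))
  v2 <- c(-10, -4, rep(NA, 26))
  out2 <- residual_correct(v2, p2, dates, comps[1, ], "d18O")
  expect_equal(out2[1:2], c(-11, -5))
  expect_equal(sum(out2[1:2] * p2[1:2]) / sum(p2[1:2]), -9)
})

test_that("correction is exact over random members", {
  set.seed(12)
  dates <- as.Date("2019-01-01") + 0:(14 * 6 - 1)
  comps <- tibble::tibble(
    window_start = dates[14 * (0:5) + 1],
    window_end = dates[14 * (1:6)],
    d18O = rnorm(6, -10, 2)
  )
  for (rep in 1:100) {
    p <- ifelse(runif(84) < 0.4, rgamma(84, 1.2, 0.2), 0)
    if (any(tapply(p, rep(1:6, each = 14), sum) == 0)) next
    v <- ifelse(p >= 0.25, rnorm(84, -10, 3), NA)
    has_wet <- tapply(p >= 0.25, rep(1:6, each = 14), any)
    out <- residual_correct(v, p, dates, comps[which(has_wet), ], "d18O")
    for (i in which(has_wet)) {
      w <- p >= 0.25 & dates >= comps$window_start[i] & dates <= comps$window_end[i]
      got <- sum(out[w] * p[w]) / sum(p[w])
      expect_lt(abs(got - comps$d18O[i]), 1e-9)
    }
  }
})
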