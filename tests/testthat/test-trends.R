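test_that("linear fits recover exact lines and enforce preconditions", {
  line <- make_annual(1:3 + 2000L, c(1, 2, 3))
  f <- suppressWarnings(fit_linear(line, allow_fewer = TRUE))
  expect_equal(unname(f$coefficients["year"]), 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_linear(line), "insufficient years")

  mixed <- rbind(make_annual(2000:2003, c(98, 97, 96, 95)),
                 make_annual(2004, 94, method = "natural_chord"))
  expect_error(fit_linear(mixed), "mix measurement methods")

  inel <- make_annual(2000:2004, c(98, 97, 96, 95, 94))
  inel$trend_eligible[2] <- FALSE
  expect_error(fit_linear(inel), "trend-ineligible")

  # duplicate years are legitimate (two sites, one region)
  dup <- make_annual(c(2000, 2000, 2001, 2002), c(98, 97, 96, 95))
  expect_equal(fit_linear(dup)$df_residual, 2)
})

test_that("OLS matches the closed-form normal-equation solution on small instances", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(3:5, 1)
    yrs <- sort(sample(1980:2015, k))
    y <- rnorm(k, 98, 2)
    tbl <- make_annual(yrs, y)
    f <- fit_linear(tbl, allow_fewer = TRUE)
    X <- cbind(1, yrs)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(f$coefficients), as.vector(beta), tolerance = 1e-7)
    if (k >= 4) {
      q <- fit_quadratic(tbl, allow_fewer = TRUE)
      Xc <- cbind(1, yrs - mean(yrs), (yrs - mean(yrs))^2)
      bc <- solve(t(Xc) %*% Xc, t(Xc) %*% y)
      expect_equal(unname(q$coefficients["year2"]), bc[3], tolerance = 1e-7)
    }
  }
})

test_that("centered and uncentered quadratic parameterizations agree in fitted values", {
  tbl <- sandpiper_annual()
  jb <- trend_subset(tbl, "wing", site_id = "james_bay", years = 1975:1982)
  q <- fit_quadratic(jb)
  centered_fit <- lm(jb$mean_mm ~ I(jb$year - mean(jb$year)) +
                       I((jb$year - mean(jb$year))^2))
  expect_lt(max(abs(predict(q) - fitted(centered_fit))), 1e-6)

  # exact unit parabola (vertex offset keeps means positive)
  par3 <- make_annual(c(1999, 2000, 2001), c(1.001, 0.001, 1.001))
  q3 <- suppressWarnings(fit_quadratic(par3, allow_fewer = TRUE))
  expect_equal(unname(q3$coefficients["year2"]), 1, tolerance = 1e-6)
  expect_equal(peak_year(q3)$year, 2000, tolerance = 1e-8)
})

test_that("quadratic vertex is located and labelled correctly", {
  yrs <- 2001:2009
  down <- make_annual(yrs, 100 - (yrs - 2005)^2 * 0.5)
  pk <- peak_year(suppressWarnings(fit_quadratic(down)))
  expect_equal(pk$year, 2005, tolerance = 1e-6)
  expect_identical(pk$type, "maximum")

  up <- make_annual(yrs, 90 + (yrs - 2004)^2 * 0.5)
  tr <- peak_year(suppressWarnings(fit_quadratic(up)))
  expect_equal(tr$year, 2004, tolerance = 1e-6)
  expect_identical(tr$type, "minimum")

  set.seed(2)
  flat <- make_annual(yrs, 98 + 0.01 * (yrs - 2005) + rnorm(9, 0, 1e-3))
  qf <- fit_quadratic(flat)
  expect_error(peak_year(qf, tol = 1), "vertex undefined")
  expect_error(peak_year(fit_linear(flat)), "quadratic")
})

test_that("ancova separates shared trends from region-specific ones", {
  yrs <- 2000:2009
  set.seed(14)
  a <- make_annual(yrs, 100 - 0.2 * (yrs - 2000) + rnorm(10, 0, 0.3),
                   region = "east")
  b <- a; b$region <- "west"; b$site_id <- "s2"
  both <- rbind(a, b)
  anc <- ancova_trend(both)  # identical regions: no interaction signal
  expect_lt(anc$interaction_F, 1e-10)
  expect_equal(anc$common_slope_mm_per_yr, unname(coef(lm(a$mean_mm ~ a$year))[2]),
               tolerance = 1e-8)

  set.seed(4)
  c1 <- make_annual(yrs, 100 - 0.1 * (yrs - 2000) + rnorm(10, 0, 1e-4),
                    region = "east")
  c2 <- make_annual(yrs, 98 - 0.3 * (yrs - 2000) + rnorm(10, 0, 1e-4),
                    region = "west", site_id = "s2")
  anc2 <- ancova_trend(rbind(c1, c2))
  expect_lt(anc2$interaction_p, 1e-6)
  expect_gt(anc2$common_slope_mm_per_yr, -0.3)
  expect_lt(anc2$common_slope_mm_per_yr, -0.1)

  single <- make_annual(2003, 99, region = "central", site_id = "s3")
  expect_warning(anc3 <- ancova_trend(rbind(c1, c2, single)),
                 "single year")
  expect_error(suppressWarnings(ancova_trend(rbind(c1, single))),
               ">= 2 regions")
})

test_that("period contrasts recover programmed offsets and the null", {
  g <- make_annual(2000:2003, c(98, 99, 97, 98.5), n = rep(60L, 4))
  self <- period_contrast(g, g)
  expect_equal(self$diff_mm, 0)
  expect_equal(self$t, 0)
  expect_equal(self$p, 1)

  delta <- 1.7
  g2 <- g; g2$mean_mm <- g$mean_mm - delta; g2$year <- g$year + 10L
  pc <- period_contrast(g, g2, "early", "late")
  expect_equal(pc$diff_mm, delta, tolerance = 1e-10)
  expect_lt(pc$p, 1e-6)
  expect_error(period_contrast(g[0, ], g2), "at least one")
})

test_that("rate projection is plain multiplication", {
  expect_equal(project_change(-0.11, 35), -3.85)
  expect_equal(project_change(0.42, 0), 0)
  expect_equal(project_change(-0.089, 35), -3.115)
})
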