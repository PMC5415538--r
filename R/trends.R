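# Trend models on annual means. The unit of analysis is the annual mean per
# site or region: fits are unweighted ordinary least squares regardless of
# the (very heterogeneous) numbers of birds behind each mean, which equalizes
# statistical power across sites. Polynomial fits are computed on centered
# years for conditioning and re-expressed in the uncentered calendar-year
# convention for reporting.

new_regression_fit <- function(model, coefficients, se, tval, pval,
                               df_residual, r_squared, f_statistic,
                               centering_offset, n_points, data, label = NULL) {
  structure(list(model = model, coefficients = coefficients, se = se,
                 t = tval, p = pval, df_residual = df_residual,
                 r_squared = r_squared, f_statistic = f_statistic,
                 centering_offset = centering_offset, n_points = n_points,
                 data = data, label = label),
            class = "regression_fit")
}

check_trend_input <- function(samples, min_years, allow_fewer) {
  if (length(unique(samples$metric)) > 1L)
    stop("samples mix metrics; fit one metric at a time", call. = FALSE)
  if (length(unique(samples$method)) > 1L)
    stop("samples mix measurement methods (",
         paste(unique(samples$method), collapse = ", "),
         "); method offsets would masquerade as trend", call. = FALSE)
  if (!all(samples$trend_eligible)) {
    bad <- samples[!samples$trend_eligible, c("site_id", "year")]
    stop("samples include trend-ineligible rows: ",
         paste(paste(bad$site_id, bad$year), collapse = ", "),
         "; filter with trend_subset() first", call. = FALSE)
  }
  if (nrow(samples) < min_years && !allow_fewer)
    stop("insufficient years: ", nrow(samples), " < ", min_years,
         " (set allow_fewer = TRUE to override)", call. = FALSE)
}

#' Fit a linear trend to annual means
#'
#' Unweighted OLS of the annual mean on calendar year. At least four years of
#' data are required by default — shorter series say little about trend — but
#' the rule can be overridden for diagnostic fits.
#'
#' @param samples trend-eligible rows of an `annual_table`, one metric and
#'   one measurement method.
#' @param min_years minimum number of annual means (default 4).
#' @param allow_fewer set `TRUE` to override the minimum-year rule.
#' @param label optional label stored in the fit (site or region name).
#' @return a `regression_fit` with uncentered `coefficients`
#'   (`intercept`, `year`), their `se`, `t`, `p`, `df_residual`,
#'   `r_squared`, and the slope's `f_statistic`.
#' @examples
#' tbl <- sandpiper_annual()
#' fit_linear(trend_subset(tbl, "wing", site_id = "nome"), label = "west")
#' @export
fit_linear <- function(samples, min_years = 4, allow_fewer = FALSE,
                       label = NULL) {
  check_trend_input(samples, min_years, allow_fewer)
  m0 <- mean(samples$year)
  xc <- samples$year - m0
  fit <- stats::lm(samples$mean_mm ~ xc)
  sm <- summary(fit)
  co <- sm$coefficients
  V <- stats::vcov(fit)
  b0c <- co[1, 1]; b1 <- co[2, 1]
  # uncentered intercept and its SE (slope is unchanged by centering)
  b0u <- b0c - b1 * m0
  se0u <- sqrt(V[1, 1] + m0^2 * V[2, 2] - 2 * m0 * V[1, 2])
  coefficients <- c(intercept = b0u, year = b1)
  se <- c(intercept = se0u, year = co[2, 2])
  tval <- coefficients / se
  df <- fit$df.residual
  pval <- 2 * stats::pt(-abs(tval), df)
  new_regression_fit(
    model = "linear", coefficients = coefficients, se = se,
    tval = tval, pval = pval, df_residual = df,
    r_squared = sm$r.squared,
    f_statistic = c(F = unname(co[2, 3]^2), df1 = 1, df2 = df),
    centering_offset = m0, n_points = nrow(samples),
    data = data.frame(year = samples$year, mean_mm = samples$mean_mm),
    label = label)
}

#' Fit a quadratic trend to annual means
#'
#' Unweighted OLS of the annual mean on year and year squared, fitted on
#' centered years (raw calendar-year design matrices for year^2 are badly
#' conditioned) and re-expressed in the uncentered convention for reporting.
#' The F statistic reported is the test of the quadratic term.
#'
#' @inheritParams fit_linear
#' @return a `regression_fit` with uncentered `coefficients`
#'   (`intercept`, `year`, `year2`).
#' @examples
#' tbl <- sandpiper_annual()
#' jb <- trend_subset(tbl, "wing", site_id = "james_bay", years = 1975:1982)
#' fit_quadratic(jb, label = "James Bay")
#' @export
fit_quadratic <- function(samples, min_years = 4, allow_fewer = FALSE,
                          label = NULL) {
  check_trend_input(samples, min_years, allow_fewer)
  m0 <- mean(samples$year)
  xc <- samples$year - m0
  fit <- stats::lm(samples$mean_mm ~ xc + I(xc^2))
  sm <- summary(fit)
  co <- sm$coefficients
  V <- stats::vcov(fit)
  b0c <- co[1, 1]; b1c <- co[2, 1]; b2 <- co[3, 1]
  # uncentered re-expression: y = b0c + b1c (x - m) + b2 (x - m)^2
  b1u <- b1c - 2 * b2 * m0
  b0u <- b0c - b1c * m0 + b2 * m0^2
  g0 <- c(1, -m0, m0^2)        # gradient of b0u wrt (b0c, b1c, b2)
  g1 <- c(0, 1, -2 * m0)
  se0u <- sqrt(drop(t(g0) %*% V %*% g0))
  se1u <- sqrt(drop(t(g1) %*% V %*% g1))
  coefficients <- c(intercept = b0u, year = b1u, year2 = b2)
  se <- c(intercept = se0u, year = se1u, year2 = co[3, 2])
  tval <- coefficients / se
  df <- fit$df.residual
  pval <- 2 * stats::pt(-abs(tval), df)
  new_regression_fit(
    model = "quadratic", coefficients = coefficients, se = se,
    tval = tval, pval = pval, df_residual = df,
    r_squared = sm$r.squared,
    f_statistic = c(F = unname(co[3, 3]^2), df1 = 1, df2 = df),
    centering_offset = m0, n_points = nrow(samples),
    data = data.frame(year = samples$year, mean_mm = samples$mean_mm),
    label = label)
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s fit%s on %d annual means (years centered at %.2f)\n",
              x$model, if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$n_points, x$centering_offset))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(signif(tab, 5))
  cat(sprintf("  r^2 = %.3f; highest-order term F[%d,%d] = %.2f\n",
              x$r_squared, x$f_statistic["df1"], x$f_statistic["df2"],
              x$f_statistic["F"]))
  invisible(x)
}

#' Fitted values of a trend fit
#'
#' @param object a `regression_fit`.
#' @param years years at which to evaluate (defaults to the fitted years).
#' @param ... unused.
#' @return numeric vector of fitted annual means.
#' @export
predict.regression_fit <- function(object, years = object$data$year, ...) {
  b <- object$coefficients
  out <- b["intercept"] + b["year"] * years
  if (object$model == "quadratic") out <- out + b["year2"] * years^2
  unname(out)
}

#' Vertex (peak or trough year) of a quadratic trend
#'
#' The stationary year of a quadratic fit, `-b / (2c)` in calendar years. The
#' vertex is a "peak" (maximum) only when the quadratic coefficient is
#' negative; otherwise it is labelled a minimum.
#'
#' @param fit a quadratic `regression_fit`.
#' @param tol quadratic coefficients smaller than this in magnitude are
#'   treated as degenerate (no defined vertex).
#' @return list with `year` (fractional calendar year) and `type`
#'   (`"maximum"` or `"minimum"`).
#' @export
peak_year <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "regression_fit"))
  if (fit$model != "quadratic")
    stop("peak_year() needs a quadratic fit", call. = FALSE)
  c2 <- unname(fit$coefficients["year2"])
  if (abs(c2) < tol)
    stop("quadratic coefficient is (near) zero: vertex undefined",
         call. = FALSE)
  b1 <- unname(fit$coefficients["year"])
  list(year = -b1 / (2 * c2), type = if (c2 < 0) "maximum" else "minimum")
}

#' ANCOVA across regions: common slope and interaction test
#'
#' Tests whether regions share a common annual rate of change. The full model
#' `mean ~ region + year + region:year` is compared to the reduced model
#' `mean ~ region + year` by an extra-sum-of-squares F test; the common slope
#' and its SE come from the reduced model, which allows region-specific
#' intercepts (the geographic size cline) but a shared trend.
#'
#' @param samples trend-eligible annual means of one metric spanning >= 2
#'   regions; regions contributing a single year are dropped with a warning.
#' @return a list of class `ancova_fit` with `common_slope_mm_per_yr`,
#'   `common_slope_se`, `common_slope_p`, `interaction_F`, `interaction_df`,
#'   `interaction_p`, `region_intercepts`, `reduced_model_F`, `reduced_df`,
#'   `reduced_p`, and `n_points` per region.
#' @examples
#' tbl <- sandpiper_annual()
#' breeding <- trend_subset(tbl, "wing", region = c("west", "central", "east"))
#' ancova_trend(breeding)
#' @export
ancova_trend <- function(samples) {
  if (length(unique(samples$metric)) > 1L)
    stop("samples mix metrics", call. = FALSE)
  if (length(unique(samples$method)) > 1L)
    stop("samples mix measurement methods", call. = FALSE)
  if (!all(samples$trend_eligible))
    stop("samples include trend-ineligible rows", call. = FALSE)
  yrs_per_region <- tapply(samples$year, samples$region,
                           function(y) length(unique(y)))
  drop <- names(yrs_per_region)[yrs_per_region < 2]
  if (length(drop) > 0L) {
    warning("dropping region(s) with a single year: ",
            paste(drop, collapse = ", "), call. = FALSE)
    samples <- samples[!samples$region %in% drop, , drop = FALSE]
  }
  if (length(unique(samples$region)) < 2L)
    stop("need >= 2 regions with >= 2 years each", call. = FALSE)
  d <- data.frame(y = samples$mean_mm, year = samples$year,
                  region = factor(samples$region))
  reduced <- stats::lm(y ~ region + year, data = d)
  full <- stats::lm(y ~ region * year, data = d)
  cmp <- stats::anova(reduced, full)
  smr <- summary(reduced)
  slope_row <- smr$coefficients["year", ]
  fstat <- smr$fstatistic
  ints <- stats::coef(reduced)
  region_int <- ints[grep("^region", names(ints))]
  structure(list(
    common_slope_mm_per_yr = unname(slope_row[1]),
    common_slope_se = unname(slope_row[2]),
    common_slope_p = unname(slope_row[4]),
    interaction_F = cmp$F[2],
    interaction_df = c(num = cmp$Df[2], den = cmp$Res.Df[2]),
    interaction_p = cmp$`Pr(>F)`[2],
    region_intercepts = region_int,
    reduced_model_F = unname(fstat[1]),
    reduced_df = c(num = unname(fstat[2]), den = unname(fstat[3])),
    reduced_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    n_points = table(d$region)),
    class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("ANCOVA on annual means\n")
  cat(sprintf("  common slope: %.3f +/- %.3f mm/yr (p = %.3g)\n",
              x$common_slope_mm_per_yr, x$common_slope_se, x$common_slope_p))
  cat(sprintf("  region x year interaction: F[%d,%d] = %.2f, p = %.3f\n",
              x$interaction_df["num"], x$interaction_df["den"],
              x$interaction_F, x$interaction_p))
  cat(sprintf("  reduced model: F[%d,%d] = %.2f, p = %.3g\n",
              x$reduced_df["num"], x$reduced_df["den"], x$reduced_model_F,
              x$reduced_p))
  invisible(x)
}

#' Early-versus-late period contrast of pooled annual samples
#'
#' Pools each group of annual samples with [pool_weighted()] and compares the
#' pooled means with a Student two-sample t test on the reconstructed
#' grouped-data variances. Because individual records are reconstructed from
#' summaries, results can differ from a raw-data test in the second decimal.
#'
#' @param group_a,group_b subsets of an `annual_table`, same metric and
#'   compatible methods.
#' @param label_a,label_b optional period labels.
#' @return a list of class `period_contrast` with the pooled summaries,
#'   `diff_mm` (A minus B), `diff_se`, `t`, `df`, `p`.
#' @export
period_contrast <- function(group_a, group_b, label_a = "A", label_b = "B") {
  if (nrow(group_a) == 0L || nrow(group_b) == 0L)
    stop("both periods need at least one annual sample", call. = FALSE)
  pa <- pool_weighted(group_a)
  pb <- pool_weighted(group_b)
  n1 <- pa$n; n2 <- pb$n
  sp2 <- ((n1 - 1) * pa$sd_mm^2 + (n2 - 1) * pb$sd_mm^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- pa$mean_mm - pb$mean_mm
  tval <- if (se == 0) 0 else diff / se
  df <- n1 + n2 - 2
  p <- if (se == 0 && diff == 0) 1 else 2 * stats::pt(-abs(tval), df)
  structure(list(
    label_a = label_a, label_b = label_b,
    years_a = sort(unique(group_a$year)), years_b = sort(unique(group_b$year)),
    pooled_a = pa, pooled_b = pb,
    diff_mm = diff, diff_se = se, t = tval, df = df, p = p),
    class = "period_contrast")
}

#' @export
print.period_contrast <- function(x, ...) {
  cat(sprintf("Period contrast: %s (%.2f +/- %.2f, N = %d) vs %s (%.2f +/- %.2f, N = %d)\n",
              x$label_a, x$pooled_a$mean_mm, x$pooled_a$se_mm, x$pooled_a$n,
              x$label_b, x$pooled_b$mean_mm, x$pooled_b$se_mm, x$pooled_b$n))
  cat(sprintf("  difference %+.2f +/- %.2f mm, t[%d] = %.2f, p = %.3g\n",
              x$diff_mm, x$diff_se, x$df, x$t, x$p))
  invisible(x)
}

#' Project a total change from an annual rate
#'
#' @param slope annual rate of change, mm per year.
#' @param span_years number of years.
#' @return total change in mm (`slope * span_years`).
#' @examples
#' project_change(-0.11, 35)  # -3.85
#' @export
project_change <- function(slope, span_years) slope * span_years
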