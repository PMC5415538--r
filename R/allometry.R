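# Bill-on-wing allometry. Almost all bill and wing measurements in these
# monitoring series were taken on the same individuals, so each site/period
# sample yields a phenotypic covariance and an allometric slope
# (cov(culmen, wing) / var(wing)); the time trend of those slopes measures
# whether shape, not just size, is changing.

#' Midpoint of a period label
#'
#' Parses period labels like `"1975-1982"`, `"2013"` or `"1991-1992, 1994"`
#' by expanding ranges, collecting the listed calendar years, and taking
#' their arithmetic mean.
#'
#' @param period character vector of period labels.
#' @return numeric vector of midpoint years.
#' @examples
#' period_midpoint("1991-1992, 1994")  # 1992.333
#' @export
period_midpoint <- function(period) {
  vapply(period, function(p) {
    parts <- trimws(strsplit(p, ",")[[1]])
    yrs <- suppressWarnings(unlist(lapply(parts, function(tok) {
      if (grepl("-", tok)) {
        ab <- as.numeric(strsplit(tok, "-")[[1]])
        if (anyNA(ab)) NA_real_ else seq(ab[1], ab[2])
      } else as.numeric(tok)
    })))
    if (any(is.na(yrs))) stop("cannot parse period '", p, "'", call. = FALSE)
    mean(yrs)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Covariance and allometric slope of paired measurements
#'
#' Sample covariance (n - 1 denominator) between wing and culmen measured on
#' the same birds, and the OLS slope of culmen on wing with its SE and
#' two-sided p value. The slope equals `cov / var(wing)` by construction.
#'
#' @param wing_mm,culmen_mm paired lengths; incomplete pairs are dropped.
#'   At least 3 complete pairs are required.
#' @param location optional site/region label.
#' @param period optional period label (see [period_midpoint()]); when given,
#'   the midpoint year is filled in.
#' @return one-row data frame of class `covariance_summary` with columns
#'   `location`, `period`, `midpoint_year`, `n_pairs`, `covariance_mm2`,
#'   `slope`, `slope_se`, `p`.
#' @examples
#' set.seed(1)
#' w <- rnorm(200, 98, 2.5)
#' b <- 15 + 0.25 * w + rnorm(200, 0, 0.6)
#' cov_slope(w, b, location = "demo", period = "2000-2004")
#' @export
cov_slope <- function(wing_mm, culmen_mm, location = NA_character_,
                      period = NA_character_) {
  keep <- !is.na(wing_mm) & !is.na(culmen_mm)
  w <- wing_mm[keep]; b <- culmen_mm[keep]
  if (length(w) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  vw <- stats::var(w)
  if (vw == 0) stop("zero wing variance: slope undefined", call. = FALSE)
  cv <- stats::cov(w, b)
  slope <- cv / vw
  fit <- summary(stats::lm(b ~ w))
  out <- data.frame(
    location = location, period = period,
    midpoint_year = if (is.na(period)) NA_real_ else period_midpoint(period),
    n_pairs = length(w), covariance_mm2 = cv, slope = slope,
    slope_se = fit$coefficients[2, 2], p = fit$coefficients[2, 4],
    stringsAsFactors = FALSE)
  class(out) <- c("covariance_summary", "data.frame")
  out
}

#' Mean allometric slope across samples
#'
#' Unweighted arithmetic mean of per-sample bill-on-wing slopes.
#'
#' @param summaries a data frame of covariance summaries with a `slope`
#'   column (e.g. [sandpiper_covariance()] or stacked [cov_slope()] rows).
#' @return mean slope (dimensionless).
#' @examples
#' mean_slope(sandpiper_covariance())  # 0.223
#' @export
mean_slope <- function(summaries) {
  if (nrow(summaries) < 1L) stop("need at least one summary", call. = FALSE)
  mean(summaries$slope)
}

#' Time trend of allometric slopes, weighted by sample size
#'
#' Weighted least squares of the per-sample bill-on-wing slope against the
#' period midpoint year, weights proportional to the number of measured
#' pairs. A negative coefficient means bills are getting relatively longer
#' than wings would predict.
#'
#' @param summaries covariance summaries with columns `slope`,
#'   `midpoint_year` (or a `period` column from which midpoints are derived)
#'   and `n_pairs`; at least 3 distinct midpoints.
#' @param weights weight per summary (default `n_pairs`).
#' @return a `regression_fit` (linear, uncentered coefficients `intercept`
#'   and `year`).
#' @examples
#' slope_trend(sandpiper_covariance())
#' @export
slope_trend <- function(summaries, weights = summaries$n_pairs) {
  mids <- summaries$midpoint_year
  if (is.null(mids) || any(is.na(mids))) {
    if (is.null(summaries$period))
      stop("summaries need midpoint_year or period", call. = FALSE)
    mids <- period_midpoint(summaries$period)
  }
  if (length(unique(mids)) < 3L)
    stop("need >= 3 summaries with distinct midpoints", call. = FALSE)
  if (length(weights) != nrow(summaries) || any(weights <= 0))
    stop("weights must be positive, one per summary", call. = FALSE)
  d <- data.frame(slope = summaries$slope, year = mids, w = weights)
  fit <- stats::lm(slope ~ year, data = d, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  coefficients <- c(intercept = co[1, 1], year = co[2, 1])
  se <- c(intercept = co[1, 2], year = co[2, 2])
  new_regression_fit(
    model = "linear", coefficients = coefficients, se = se,
    tval = coefficients / se,
    pval = c(co[1, 4], co[2, 4]),
    df_residual = fit$df.residual, r_squared = sm$r.squared,
    f_statistic = c(F = unname(co[2, 3]^2), df1 = 1, df2 = fit$df.residual),
    centering_offset = 0, n_points = nrow(d),
    data = data.frame(year = d$year, mean_mm = d$slope),
    label = "allometric slope ~ midpoint year (weighted)")
}

#' Read a covariance-summary table from CSV
#'
#' @param path CSV with columns `location`, `period`, `n_pairs`,
#'   `covariance_mm2`, `slope` (optionally `slope_se`, `p`).
#' @return `covariance_summary` data frame with `midpoint_year` filled in.
#' @export
read_covariance_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("location", "period", "n_pairs", "covariance_mm2", "slope")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("covariance table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$midpoint_year <- period_midpoint(df$period)
  if (!"slope_se" %in% names(df)) df$slope_se <- NA_real_
  if (!"p" %in% names(df)) df$p <- NA_real_
  class(df) <- c("covariance_summary", "data.frame")
  df
}
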