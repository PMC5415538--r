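# Synthetic morphometric data generator. Emulates the statistical structure
# the pipeline assumes — female-biased size dimorphism with a common
# within-sex SD, east-west size clines, piecewise-linear year trends with a
# breakpoint, wing measurement-method offsets, site-level observer biases,
# stopover-site mixing of breeding origins, and seasonally biased sex ratios
# — so every stage is testable with known ground truth.

#' Invert pooled moments into per-sex statistics
#'
#' Sexual dimorphism is modelled as a pure location shift with a common
#' within-sex SD. For an equal-mix two-component normal with means
#' `m -/+ offset/2` and common SD `s`, the pooled moments are
#' `mean = m` and `var = s^2 + offset^2 / 4`; this function inverts that
#' relation so that a simulated pooled draw reproduces published pooled
#' values.
#'
#' @param pooled_mean_mm,pooled_sd_mm target pooled mean and SD.
#' @param dimorphism_offset_mm female-minus-male mean difference (mm);
#'   requires `pooled_sd^2 > offset^2 / 4`.
#' @param region,metric labels passed through to the stats.
#' @param n_male,n_female specimen counts recorded in the stats.
#' @return list with `male` and `female` [sex_group_stats()].
#' @examples
#' calibrate_sex_stats(98, 2.828427, 4)  # sexes (96, 2) and (100, 2)
#' @export
calibrate_sex_stats <- function(pooled_mean_mm, pooled_sd_mm,
                                dimorphism_offset_mm,
                                region = "central", metric = "wing",
                                n_male = 1000, n_female = 1000) {
  if (pooled_sd_mm^2 <= dimorphism_offset_mm^2 / 4)
    stop("dimorphism offset too large: needs pooled_sd^2 > offset^2/4",
         call. = FALSE)
  s <- sqrt(pooled_sd_mm^2 - dimorphism_offset_mm^2 / 4)
  list(
    male = sex_group_stats(region, "M", metric, n_male,
                           pooled_mean_mm - dimorphism_offset_mm / 2, s),
    female = sex_group_stats(region, "F", metric, n_female,
                             pooled_mean_mm + dimorphism_offset_mm / 2, s))
}

#' Default synthetic-data configuration
#'
#' Returns the generator configuration as a validated list. Defaults are the
#' study conditions the packaged example data describe: regional pooled
#' means/SDs matching the historical museum rows, a piecewise wing trend
#' rising to a 1980 breakpoint and declining at 0.11 mm/yr after it, a flat
#' culmen trend, a -2.5 mm natural-chord wing offset, female-larger
#' dimorphism, and a bill-on-wing allometric slope of 0.223 that declines by
#' 0.0056 per year.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   replaced wholesale; pass complete sub-lists).
#' @return a list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(years = 1990:1999, birds_per_year = 50, seed = 7)
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    regions = list(
      west = list(wing = c(mean = 96.66, sd = 2.48),
                  culmen = c(mean = 18.27, sd = 1.02)),
      central = list(wing = c(mean = 97.40, sd = 3.03),
                     culmen = c(mean = 18.86, sd = 1.18)),
      east = list(wing = c(mean = 99.34, sd = 2.92),
                  culmen = c(mean = 20.65, sd = 1.25))),
    dimorphism_mm = c(wing = 2.5, culmen = 1.2),
    reference_year = 1960,
    trend = list(
      wing = c(breakpoint = 1980, slope_pre = 0.05, slope_post = -0.11),
      culmen = c(breakpoint = 1980, slope_pre = 0, slope_post = 0)),
    allometry = list(slope_reference = 0.223, reference_year = 1995,
                     change_per_year = -0.0056),
    method_offset = list(natural_chord = -2.5, proportional = FALSE,
                         proportion = -0.022),
    observer_bias = list(),
    sex_ratio = list(p_female = 0.5, seasonal_bias = 0,
                     season_length_days = 40),
    sites = data.frame(
      site_id = c("west_site", "central_site", "east_site"),
      region = c("west", "central", "east"),
      method = "flattened", stringsAsFactors = FALSE),
    stopover_mix = list(),
    years = 1980:2014,
    birds_per_year = 100,
    seed = 42)
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg))
      stop("unknown config field: ", nm, call. = FALSE)
    cfg[[nm]] <- overrides[[nm]]
  }
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

#' Validate a synthetic-data configuration
#'
#' @param cfg a `synthetic_config`.
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  for (rg in names(cfg$regions)) {
    for (met in names(cfg$regions[[rg]])) {
      v <- cfg$regions[[rg]][[met]]
      if (!all(c("mean", "sd") %in% names(v)) || v["sd"] <= 0 || v["mean"] <= 0)
        stop("invalid config field regions$", rg, "$", met,
             ": needs positive mean and sd", call. = FALSE)
      off <- cfg$dimorphism_mm[[met]]
      if (v["sd"]^2 <= off^2 / 4)
        stop("invalid config field dimorphism_mm[", met,
             "]: offset too large for pooled sd in region ", rg,
             call. = FALSE)
    }
  }
  for (met in names(cfg$trend)) {
    tr <- cfg$trend[[met]]
    if (!all(c("breakpoint", "slope_pre", "slope_post") %in% names(tr)))
      stop("invalid config field trend$", met, call. = FALSE)
    if (cfg$reference_year > tr[["breakpoint"]])
      stop("invalid config field reference_year: must be <= trend breakpoint",
           call. = FALSE)
  }
  sr <- cfg$sex_ratio
  if (sr$p_female <= 0 || sr$p_female >= 1)
    stop("invalid config field sex_ratio$p_female: must be in (0,1)",
         call. = FALSE)
  if (sr$season_length_days <= 0)
    stop("invalid config field sex_ratio$season_length_days", call. = FALSE)
  if (cfg$birds_per_year < 1)
    stop("invalid config field birds_per_year", call. = FALSE)
  if (!all(cfg$sites$region %in% c(names(cfg$regions), "stopover")))
    stop("invalid config field sites$region", call. = FALSE)
  for (sid in cfg$sites$site_id[cfg$sites$region == "stopover"]) {
    mix <- cfg$stopover_mix[[sid]]
    if (is.null(mix) || abs(sum(mix) - 1) > 1e-8 ||
        !all(names(mix) %in% names(cfg$regions)))
      stop("invalid config field stopover_mix$", sid,
           ": proportions over breeding regions must sum to 1",
           call. = FALSE)
  }
  invisible(cfg)
}

# piecewise-linear trend offset relative to the reference year
trend_offset <- function(cfg, metric, year) {
  tr <- cfg$trend[[metric]]
  bp <- tr[["breakpoint"]]
  tr[["slope_pre"]] * (pmin(year, bp) - cfg$reference_year) +
    tr[["slope_post"]] * pmax(0, year - bp)
}

#' Generate synthetic individual capture records
#'
#' For each configured site and year, draws a capture date, a sex from the
#' (possibly seasonally biased) sex-ratio model, a breeding-region origin
#' (for stopover sites, from the configured mixture), and wing and culmen
#' lengths from sex-specific normals centred on the region mean plus the
#' year's trend offset, with the wing measurement-method and observer
#' offsets applied. Culmen values are coupled to the bird's wing deviation
#' through the configured allometric slope. Deterministic per seed.
#'
#' @param cfg a `synthetic_config`.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return an individual-record data frame (see [validate_individuals()])
#'   with extra columns `origin_region` and `capture_date`.
#' @export
generate_individuals <- function(cfg, seed = cfg$seed) {
  validate_config(cfg)
  with_seed(seed, {
    rows <- vector("list", nrow(cfg$sites) * length(cfg$years))
    k <- 0L
    for (i in seq_len(nrow(cfg$sites))) {
      sid <- cfg$sites$site_id[i]
      sreg <- cfg$sites$region[i]
      method <- cfg$sites$method[i]
      nb <- if ("birds_per_year" %in% names(cfg$sites))
        cfg$sites$birds_per_year[i] else cfg$birds_per_year
      obs <- cfg$observer_bias[[sid]] %||% 0
      for (yr in cfg$years) {
        L <- cfg$sex_ratio$season_length_days
        date <- stats::runif(nb, 0, L)
        pf <- stats::plogis(stats::qlogis(cfg$sex_ratio$p_female) -
                              cfg$sex_ratio$seasonal_bias *
                              (date - L / 2) / (L / 2))
        sex <- ifelse(stats::rbinom(nb, 1, pf) == 1, "F", "M")
        origin <- if (sreg == "stopover") {
          mix <- cfg$stopover_mix[[sid]]
          sample(names(mix), nb, replace = TRUE, prob = mix)
        } else rep(sreg, nb)

        wing <- numeric(nb); culmen <- numeric(nb)
        for (rg in unique(origin)) {
          ii <- origin == rg
          base <- cfg$regions[[rg]]
          sgn <- ifelse(sex[ii] == "F", 0.5, -0.5)
          off_w <- cfg$dimorphism_mm[["wing"]]
          off_c <- cfg$dimorphism_mm[["culmen"]]
          sd_w <- sqrt(base$wing[["sd"]]^2 - off_w^2 / 4)
          sd_c <- sqrt(base$culmen[["sd"]]^2 - off_c^2 / 4)
          mu_w <- base$wing[["mean"]] + sgn * off_w +
            trend_offset(cfg, "wing", yr)
          mu_c <- base$culmen[["mean"]] + sgn * off_c +
            trend_offset(cfg, "culmen", yr)
          dev_w <- stats::rnorm(sum(ii), 0, sd_w)
          b <- cfg$allometry$slope_reference +
            cfg$allometry$change_per_year * (yr - cfg$allometry$reference_year)
          sd_resid <- sqrt(pmax(sd_c^2 - b^2 * sd_w^2, 1e-4))
          wing[ii] <- mu_w + dev_w
          culmen[ii] <- mu_c + b * dev_w + stats::rnorm(sum(ii), 0, sd_resid)
        }
        # method/observer offsets affect the recorded wing value only
        m_off <- if (isTRUE(cfg$method_offset$proportional)) {
          if (method == "natural_chord") wing * cfg$method_offset$proportion
          else 0
        } else cfg$method_offset[[method]] %||% 0
        wing <- wing + m_off + obs

        k <- k + 1L
        rows[[k]] <- data.frame(
          record_id = sprintf("%s_%d_%03d", sid, yr, seq_len(nb)),
          site_id = sid, region = sreg, year = yr, sex = sex,
          wing_mm = wing, culmen_mm = culmen, method = method,
          source = "live", shrinkage_applied = FALSE,
          origin_region = origin, capture_date = date,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows[seq_len(k)])
    rownames(out) <- NULL
    validate_individuals(out)
    out
  })
}

#' Generate a synthetic annual summary table
#'
#' Applies [summarize_annual()] to generated individuals, producing a table
#' shaped like the packaged annual fixture.
#'
#' @param cfg a `synthetic_config`.
#' @param individuals optionally, records already produced by
#'   [generate_individuals()]; generated from `cfg` when omitted.
#' @return an `annual_table`.
#' @export
generate_annual_table <- function(cfg, individuals = NULL) {
  if (is.null(individuals)) individuals <- generate_individuals(cfg)
  combos <- unique(individuals[, c("site_id", "year")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    for (met in .metrics) {
      rows[[length(rows) + 1L]] <-
        summarize_annual(individuals, combos$site_id[i], combos$year[i], met)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("annual_table", "data.frame")
  validate_annual_table(out)
  out
}
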