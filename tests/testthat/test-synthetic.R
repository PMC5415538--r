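test_that("sex-stat calibration inverts the mixture moments", {
  cal <- calibrate_sex_stats(98, sqrt(8), 4)
  expect_equal(cal$male$mean_mm, 96)
  expect_equal(cal$female$mean_mm, 100)
  expect_equal(cal$male$sd_mm, 2, tolerance = 1e-10)

  zero <- calibrate_sex_stats(97.4, 3.03, 0)
  expect_equal(zero$male$mean_mm, 97.4)
  expect_equal(zero$male$sd_mm, 3.03)
  expect_equal(zero$female$mean_mm, 97.4)

  expect_error(calibrate_sex_stats(98, 1, 4), "offset too large")
})

test_that("calibrate -> simulate -> pool round-trips the pooled inputs", {
  cal <- calibrate_sex_stats(97.4, 3.03, 2.5, region = "central",
                             metric = "wing")
  b <- simulate_baseline(cal$male, cal$female, n_per_sex = 1e5, seed = 17)
  expect_equal(b$pooled_mean_mm, 97.4, tolerance = 0.05)
  expect_equal(b$pooled_sd_mm, 3.03, tolerance = 0.05)
})

test_that("generation is deterministic per seed and validated by field", {
  cfg <- synthetic_config(years = 1995:1999, birds_per_year = 20, seed = 12)
  a <- generate_individuals(cfg)
  b <- generate_individuals(cfg)
  expect_identical(a, b)
  c2 <- generate_individuals(cfg, seed = 13)
  expect_false(identical(a$wing_mm, c2$wing_mm))

  expect_error(synthetic_config(nonsense = 1), "unknown config field")
  expect_error(synthetic_config(birds_per_year = 0), "birds_per_year")
  expect_error(
    synthetic_config(dimorphism_mm = c(wing = 20, culmen = 1.2)),
    "dimorphism_mm\\[wing\\]")
  expect_error(
    synthetic_config(sex_ratio = list(p_female = 1.2, seasonal_bias = 0,
                                      season_length_days = 40)),
    "p_female")
  expect_error(
    synthetic_config(
      sites = data.frame(site_id = "x", region = "stopover",
                         method = "flattened"),
      stopover_mix = list(x = c(west = 0.7))),
    "stopover_mix")
})

test_that("programmed trends are recovered from generated annual means", {
  # null trend: fitted slope is statistically indistinguishable from zero
  flat <- synthetic_config(
    trend = list(wing = c(breakpoint = 1980, slope_pre = 0, slope_post = 0),
                 culmen = c(breakpoint = 1980, slope_pre = 0, slope_post = 0)),
    years = 1985:2009, birds_per_year = 80, seed = 23)
  ann0 <- generate_annual_table(flat)
  f0 <- fit_linear(trend_subset(ann0, "wing", site_id = "west_site"))
  expect_lt(abs(unname(f0$coefficients["year"])),
            2 * unname(f0$se["year"]))

  # programmed post-1980 decline recovered within 2 SE
  cfg <- synthetic_config(years = 1981:2010, birds_per_year = 100, seed = 3)
  ann <- generate_annual_table(cfg)
  f <- fit_linear(trend_subset(ann, "wing", site_id = "central_site"))
  expect_lt(abs(unname(f$coefficients["year"]) - (-0.11)),
            2 * unname(f$se["year"]))

  # piecewise rise-then-fall shows up as a concave quadratic with a vertex
  # near the programmed breakpoint
  pw <- synthetic_config(years = 1960:1999, birds_per_year = 150, seed = 29)
  annp <- generate_annual_table(pw)
  q <- fit_quadratic(trend_subset(annp, "wing", site_id = "east_site"))
  pk <- peak_year(q)
  expect_identical(pk$type, "maximum")
  expect_lt(abs(pk$year - 1980), 4)
})

test_that("generated summaries carry the configured moments", {
  cfg <- synthetic_config(years = 1960, birds_per_year = 1e4, seed = 41)
  ann <- generate_annual_table(cfg)
  central <- ann[ann$site_id == "central_site" & ann$metric == "wing", ]
  # at the reference year the trend offset is zero: pooled config values
  expect_equal(central$mean_mm, 97.4, tolerance = 0.1)
  expect_lt(abs(central$se_mm - 3.03 / sqrt(1e4)), 0.15 * 0.0303)

  # regional cline is preserved: east > central > west wings
  means <- sapply(c("west_site", "central_site", "east_site"), function(s)
    ann$mean_mm[ann$site_id == s & ann$metric == "wing"])
  expect_true(means["west_site"] < means["central_site"] &&
                means["central_site"] < means["east_site"])
})

test_that("seasonal sex-ratio bias makes females earlier and shifts late means", {
  cfg <- synthetic_config(
    sex_ratio = list(p_female = 0.5, seasonal_bias = 2,
                     season_length_days = 40),
    years = 2000:2004, birds_per_year = 400, seed = 19)
  ind <- generate_individuals(cfg)
  expect_lt(mean(ind$capture_date[ind$sex == "F"]),
            mean(ind$capture_date[ind$sex == "M"]))
  # female-biased dimorphism + male-biased late season: late means run lower
  late <- ind$capture_date > 20
  expect_lt(mean(ind$wing_mm[late]), mean(ind$wing_mm[!late]))
})

test_that("stopover sites mix breeding origins and method offsets apply", {
  cfg <- synthetic_config(
    sites = data.frame(
      site_id = c("east_site", "stop"), region = c("east", "stopover"),
      method = c("flattened", "natural_chord"), stringsAsFactors = FALSE),
    stopover_mix = list(stop = c(west = 0.25, central = 0.25, east = 0.5)),
    years = 2000:2001, birds_per_year = 2000, seed = 37)
  ind <- generate_individuals(cfg)
  stop_ind <- ind[ind$site_id == "stop", ]
  prop_east <- mean(stop_ind$origin_region == "east")
  expect_equal(prop_east, 0.5, tolerance = 0.05)
  # natural-chord offset: east-origin birds at the stopover read ~2.5 mm
  # shorter than the same cohort measured flattened at the breeding site
  east_at_stop <- mean(stop_ind$wing_mm[stop_ind$origin_region == "east"])
  east_at_home <- mean(ind$wing_mm[ind$site_id == "east_site"])
  expect_equal(east_at_home - east_at_stop, 2.5, tolerance = 0.4)
})
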