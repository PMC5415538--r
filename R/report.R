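# Reporting layer. All rounding to printed precision happens here, at
# emission — upstream objects keep full floating-point precision.

#' Format p values for report tables
#'
#' Three decimals with values below .001 floored to `"<.001"`.
#'
#' @param p numeric p values.
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p)))
}

#' Tabulate resampled historical comparisons
#'
#' Stacks [resampled_comparison()] results into a report table: region,
#' metric, live years, sample sizes, mean difference (2 decimals), mean t
#' (2 decimals) and mean p.
#'
#' @param results list of `comparison_result` objects.
#' @param years optional character vector of live-year labels, one per
#'   result.
#' @return data frame.
#' @export
comparison_table <- function(results, years = NULL) {
  stopifnot(all(vapply(results, inherits, logical(1), "comparison_result")))
  out <- data.frame(
    region = vapply(results, `[[`, character(1), "region"),
    metric = vapply(results, `[[`, character(1), "metric"),
    years = years %||% rep(NA_character_, length(results)),
    n_random = vapply(results, `[[`, integer(1), "resample_n"),
    mean_diff_mm = sprintf("%+.2f", vapply(results, `[[`, numeric(1),
                                           "mean_diff_mm")),
    mean_t = round(vapply(results, `[[`, numeric(1), "mean_t"), 2),
    mean_p = format_p(vapply(results, `[[`, numeric(1), "mean_p")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tabulate trend fits
#'
#' Stacks `regression_fit` objects into a report table mirroring the usual
#' slope/SE/t/p layout; slopes to 3 decimals, t to 2, p floored at `"<.001"`.
#' Quadratic fits report their year and year-squared terms.
#'
#' @param fits list of `regression_fit` objects.
#' @param labels optional labels overriding each fit's own.
#' @return data frame.
#' @export
trend_table <- function(fits, labels = NULL) {
  stopifnot(all(vapply(fits, inherits, logical(1), "regression_fit")))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    lab <- labels[i] %||% (f$label %||% NA_character_)
    yrs <- paste0(min(f$data$year), "-", max(f$data$year))
    data.frame(
      location = lab, years = yrs, model = f$model,
      slope = round(unname(f$coefficients["year"]), 3),
      se = round(unname(f$se["year"]), 3),
      t = round(unname(f$t["year"]), 2),
      p = format_p(unname(f$p["year"])),
      year2 = if (f$model == "quadratic")
        signif(unname(f$coefficients["year2"]), 4) else NA_real_,
      n_years = f$n_points,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate covariance summaries
#'
#' @param summaries a `covariance_summary` data frame; a mean-slope row is
#'   appended.
#' @return data frame with covariance and slope rounded to 3 decimals.
#' @export
covariance_table <- function(summaries) {
  out <- data.frame(
    location = summaries$location, period = summaries$period,
    n = summaries$n_pairs,
    covariance = round(summaries$covariance_mm2, 3),
    slope = round(summaries$slope, 3), stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(location = "Mean slope", period = "", n = NA,
                               covariance = NA,
                               slope = round(mean_slope(summaries), 3)))
  rownames(out) <- NULL
  out
}

#' Build a run manifest
#'
#' Records what produced a set of artifacts: the command, a hash of the
#' configuration, checksums of the input files, the seed(s), the package
#' version and a UTC timestamp. Every emitted result file should reference
#' exactly one manifest.
#'
#' @param command short command label (e.g. `"simulate"`, `"report"`).
#' @param config configuration object (hashed after deparse), or `NULL`.
#' @param inputs character vector of input file paths (checksummed).
#' @param seed seed(s) used.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = NULL, inputs = character(),
                         seed = NULL) {
  cfg_hash <- if (is.null(config)) NA_character_ else {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(deparse(config), tmp)
    unname(tools::md5sum(tmp))
  }
  checksums <- if (length(inputs) > 0) {
    cs <- tools::md5sum(inputs)
    stats::setNames(unname(cs), basename(inputs))
  } else NULL
  structure(list(
    command = command, config_hash = cfg_hash,
    input_checksums = as.list(checksums %||% stats::setNames(list(), character(0))),
    seed = seed,
    package_version = as.character(utils::packageVersion("wingtrends")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    class = "run_manifest")
}

#' Write report tables and a manifest to a directory
#'
#' Writes each table as CSV (atomically: to a temporary file, then renamed)
#' plus `manifest.json`.
#'
#' @param tables named list of data frames; each is written as
#'   `<name>.csv`.
#' @param dir output directory, created if needed.
#' @param manifest a `run_manifest`.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(tables, dir, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    tmp <- paste0(path, ".tmp")
    utils::write.csv(tables[[nm]], tmp, row.names = FALSE, na = "")
    file.rename(tmp, path)
    written <- c(written, path)
  }
  mpath <- file.path(dir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(unclass(manifest), tmp, auto_unbox = TRUE,
                       null = "null", digits = NA)
  file.rename(tmp, mpath)
  invisible(c(written, mpath))
}

#' Run the packaged example analysis end to end
#'
#' Composes the pipeline on an annual table: linear trend fits per breeding
#' region and stopover site, the breeding-region ANCOVA, the stopover
#' quadratics, and the allometric slope trend; writes the three report
#' tables and a manifest. This is the function behind the `report`
#' subcommand of the shipped command-line script.
#'
#' @param annual an `annual_table` (defaults to the packaged data).
#' @param covariance a `covariance_summary` table (defaults to packaged).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed seed recorded in the manifest.
#' @return named list of the report tables, invisibly when writing.
#' @export
run_report <- function(annual = sandpiper_annual(),
                       covariance = sandpiper_covariance(),
                       out_dir = NULL, seed = 1) {
  eligible <- annual[annual$trend_eligible, , drop = FALSE]
  if (nrow(eligible) == 0L) stop("no eligible samples", call. = FALSE)
  fits <- list()
  for (rg in intersect(c("west", "central", "east"), unique(eligible$region))) {
    sub <- trend_subset(annual, "wing", region = rg)
    if (nrow(sub) >= 4) fits[[rg]] <- fit_linear(sub, label = rg)
  }
  for (sid in unique(eligible$site_id[eligible$region == "stopover"])) {
    sub <- trend_subset(annual, "wing", site_id = sid)
    if (nrow(sub) >= 4)
      fits[[sid]] <- fit_linear(sub, label = sid)
  }
  tables <- list(
    trend_fits = trend_table(fits),
    covariance_summaries = covariance_table(covariance))
  breeding <- trend_subset(annual, "wing",
                           region = c("west", "central", "east"))
  if (length(unique(breeding$region)) >= 2) {
    anc <- ancova_trend(breeding)
    tables$ancova <- data.frame(
      common_slope = round(anc$common_slope_mm_per_yr, 3),
      se = round(anc$common_slope_se, 3),
      interaction_F = round(anc$interaction_F, 2),
      interaction_p = format_p(anc$interaction_p))
  }
  if (!is.null(out_dir)) {
    manifest <- run_manifest("report", inputs = character(0), seed = seed)
    write_report(tables, out_dir, manifest)
    return(invisible(tables))
  }
  tables
}
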