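#' Validate an annual summary table
#'
#' Checks the invariants of a site-by-year-by-metric summary table: required
#' columns, enum levels, positive means, non-negative standard errors, counts
#' of at least one bird, and the rule that a wing series measured with mixed
#' or unknown technique is never trend-eligible.
#'
#' @param tbl data frame of annual samples.
#' @return `tbl`, invisibly, with class `annual_table` prepended.
#' @export
validate_annual_table <- function(tbl) {
  required <- c("site_id", "region", "year", "metric", "method",
                "mean_mm", "se_mm", "n", "trend_eligible", "exclusion_reason")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L)
    stop("annual table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("mean_mm", "se_mm", "n", "year")) {
    bad <- which(!is.na(tbl[[col]]) & is.na(suppressWarnings(as.numeric(tbl[[col]]))))
    bad <- union(bad, which(is.na(tbl[[col]])))
    if (length(bad) > 0L)
      stop("non-numeric or missing '", col, "' in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(tbl$region %in% .regions))
    stop("unknown region level(s): ",
         paste(setdiff(unique(tbl$region), .regions), collapse = ", "),
         call. = FALSE)
  if (!all(tbl$metric %in% .metrics))
    stop("unknown metric level(s): ",
         paste(setdiff(unique(tbl$metric), .metrics), collapse = ", "),
         call. = FALSE)
  if (!all(tbl$method %in% .methods))
    stop("unknown method level(s): ",
         paste(setdiff(unique(tbl$method), .methods), collapse = ", "),
         call. = FALSE)
  if (any(tbl$n < 1)) stop("all samples must have n >= 1", call. = FALSE)
  if (any(tbl$se_mm < 0)) stop("se_mm must be >= 0", call. = FALSE)
  if (any(tbl$mean_mm <= 0)) stop("mean_mm must be > 0", call. = FALSE)
  bad <- tbl$metric == "wing" & tbl$method == "mixed_unknown" & tbl$trend_eligible
  if (any(bad))
    stop("wing samples with method 'mixed_unknown' can never be ",
         "trend-eligible (row(s) ", paste(which(bad), collapse = ", "), ")",
         call. = FALSE)
  if (!inherits(tbl, "annual_table")) class(tbl) <- c("annual_table", class(tbl))
  invisible(tbl)
}

#' Read an annual summary table from CSV
#'
#' Reads a delimited text file with one row per site, year and metric, giving
#' the annual mean, its standard error and the number of birds measured.
#' Footnote-style exclusions are carried as the `trend_eligible` flag plus a
#' free-text `exclusion_reason`, so alternative inclusion analyses are a data
#' edit rather than a code change. Row order is preserved.
#'
#' @param path path to a CSV file with header.
#' @param schema optional named character vector mapping file column names to
#'   the canonical names (`c(mean_mm = "avg")` reads column `avg` as
#'   `mean_mm`).
#' @return a `data.frame` of class `annual_table` with columns `site_id`,
#'   `region`, `year`, `metric`, `method`, `mean_mm`, `se_mm`, `n`,
#'   `trend_eligible`, `exclusion_reason`.
#' @seealso [write_annual_table()], [sandpiper_annual()]
#' @examples
#' tbl <- sandpiper_annual()
#' head(tbl)
#' @export
read_annual_table <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema column '", src, "' not found in file", call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("site_id", "region", "year", "metric", "method",
                "mean_mm", "se_mm", "n", "trend_eligible", "exclusion_reason")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("annual table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tbl <- raw[, required]
  for (col in c("year", "mean_mm", "se_mm", "n")) {
    val <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(val))
    if (length(bad) > 0L)
      stop("non-numeric '", col, "' in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    tbl[[col]] <- val
  }
  tbl$year <- as.integer(tbl$year)
  tbl$n <- as.integer(tbl$n)
  tbl$trend_eligible <- as.logical(tbl$trend_eligible)
  tbl$exclusion_reason <- as.character(tbl$exclusion_reason)
  tbl$exclusion_reason[!is.na(tbl$exclusion_reason) &
                         tbl$exclusion_reason == ""] <- NA_character_
  validate_annual_table(tbl)
  class(tbl) <- c("annual_table", "data.frame")
  tbl
}

#' Write an annual summary table to CSV
#'
#' Inverse of [read_annual_table()]: a write followed by a read reproduces all
#' fields exactly.
#'
#' @param tbl an `annual_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annual_table <- function(tbl, path) {
  validate_annual_table(tbl)
  out <- as.data.frame(tbl)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize individual records into an annual sample
#'
#' Collapses individual measurements for one site, year and metric to the
#' annual mean, its standard error (sample SD / sqrt(n)) and the bird count —
#' the unit of analysis for all trend fitting. Records measured with
#' different techniques must not be mixed in one summary; doing so raises an
#' error rather than a warning because method offsets (e.g. natural vs
#' flattened wing chord) are larger than the trends of interest.
#'
#' @param records individual-record data frame (see [generate_individuals()]
#'   for the column layout).
#' @param site_id,year site and calendar year to summarize.
#' @param metric `"wing"` or `"culmen"`.
#' @return a one-row `annual_table` data frame.
#' @export
summarize_annual <- function(records, site_id, year, metric) {
  metric <- match.arg(metric, .metrics)
  sel <- records$site_id == site_id & records$year == year
  col <- paste0(metric, "_mm")
  vals <- records[[col]][sel]
  keep <- !is.na(vals)
  vals <- vals[keep]
  methods <- unique(records$method[sel][keep])
  if (length(vals) < 2L)
    stop("need at least 2 records with ", metric, " present for ",
         site_id, " ", year, call. = FALSE)
  if (length(methods) > 1L)
    stop("mixed measurement methods (", paste(methods, collapse = ", "),
         ") in one annual summary for ", site_id, " ", year,
         call. = FALSE)
  region <- unique(records$region[sel][keep])
  if (length(region) != 1L) region <- "stopover"
  out <- data.frame(
    site_id = site_id, region = region, year = as.integer(year),
    metric = metric, method = methods,
    mean_mm = mean(vals),
    se_mm = stats::sd(vals) / sqrt(length(vals)),
    n = length(vals),
    trend_eligible = methods != "mixed_unknown",
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("annual_table", "data.frame")
  out
}

#' Pool annual samples into a single grouped summary
#'
#' Combines several annual summaries of the same metric into one pooled mean,
#' SD and SE, reconstructing each year's individual-level variance from its
#' standard error (`sd_i^2 = n_i * se_i^2`) and combining within- and
#' between-year components as a grouped-data variance. This reconstruction is
#' an approximation to pooling the raw records, exact when the summaries were
#' themselves computed with [summarize_annual()].
#'
#' @param samples an `annual_table` (or subset) of one metric with compatible
#'   measurement methods.
#' @return list with elements `mean_mm`, `sd_mm`, `se_mm`, `n`.
#' @examples
#' jb <- subset(sandpiper_annual(), site_id == "james_bay" &
#'   metric == "wing" & year >= 2014)
#' pool_weighted(jb)
#' @export
pool_weighted <- function(samples) {
  if (nrow(samples) == 0L) stop("cannot pool an empty set of samples",
                                call. = FALSE)
  if (length(unique(samples$metric)) > 1L)
    stop("cannot pool across metrics", call. = FALSE)
  if (length(unique(samples$method)) > 1L)
    stop("cannot pool across measurement methods", call. = FALSE)
  n <- samples$n
  m <- samples$mean_mm
  v <- samples$se_mm^2 * n            # per-year individual variance
  N <- sum(n)
  M <- sum(n * m) / N
  ss <- sum((n - 1) * v + n * (m - M)^2)
  sd_p <- if (N > 1) sqrt(ss / (N - 1)) else 0
  list(mean_mm = M, sd_mm = sd_p, se_mm = sd_p / sqrt(N), n = N)
}

#' Select trend-eligible samples
#'
#' Convenience filter used before trend fitting: restricts an annual table to
#' one metric, optionally one site or region and year range, and keeps only
#' rows flagged `trend_eligible`.
#'
#' @param tbl an `annual_table`.
#' @param metric `"wing"` or `"culmen"`.
#' @param site_id,region optional filters.
#' @param years optional integer vector of years to keep.
#' @return the filtered `annual_table`.
#' @export
trend_subset <- function(tbl, metric, site_id = NULL, region = NULL,
                         years = NULL) {
  metric0 <- match.arg(metric, .metrics)
  sel <- tbl$metric == metric0 & tbl$trend_eligible
  if (!is.null(site_id)) sel <- sel & tbl$site_id %in% site_id
  if (!is.null(region)) sel <- sel & tbl$region %in% region
  if (!is.null(years)) sel <- sel & tbl$year %in% years
  out <- tbl[sel, , drop = FALSE]
  class(out) <- c("annual_table", "data.frame")
  out
}
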