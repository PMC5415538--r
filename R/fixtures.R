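# Packaged example data: annual means, pooled historical museum rows, and
# per-sample bill-wing covariance summaries transcribed from a published
# five-decade semipalmated sandpiper morphometric compilation.

#' Packaged semipalmated sandpiper annual means
#'
#' One row per site, year and metric: annual mean, SE, bird count,
#' measurement method, and the trend-eligibility flag encoding the published
#' exclusions (limited-effort years, measurement-technique changes, one
#' duplicated site record).
#'
#' @return an `annual_table`.
#' @export
sandpiper_annual <- function() {
  read_annual_table(system.file("extdata", "table1_annual.csv",
                                package = "wingtrends", mustWork = TRUE))
}

#' Packaged historical pooled museum distributions
#'
#' Regional sex-pooled mean and SD of the simulated historical size
#' distributions, with the number of museum specimens originally measured.
#'
#' @return data frame with columns `region`, `metric`, `n_specimens`,
#'   `mean_mm`, `sd_mm`.
#' @export
sandpiper_historical <- function() {
  utils::read.csv(system.file("extdata", "table1_historical.csv",
                              package = "wingtrends", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Packaged bill-wing covariance summaries
#'
#' Phenotypic covariance and bill-on-wing slope per site/period sample, with
#' period midpoints derived from the period labels.
#'
#' @return a `covariance_summary` data frame.
#' @export
sandpiper_covariance <- function() {
  read_covariance_table(system.file("extdata", "table4_covariance.csv",
                                    package = "wingtrends", mustWork = TRUE))
}
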