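# Standardized evolutionary rates. Both statistics are dimensionless in the
# length units: darwins divide a proportional (or log) change by elapsed time
# in millions of years; haldanes divide a change in pooled-SD units by
# elapsed generations.

#' Rate of phenotypic change in haldanes
#'
#' Change expressed in pooled phenotypic standard deviations per generation:
#' `(delta / pooled_sd) / (span / generation_time)`. The sign follows the
#' sign of the change, and the value is invariant under any common rescaling
#' of the length inputs.
#'
#' @param delta_mm total change in the trait (mm; signed).
#' @param pooled_sd_mm pooled phenotypic standard deviation (mm, > 0).
#' @param span_years elapsed time (years, > 0).
#' @param generation_time_years generation time (years, > 0).
#' @return rate in haldanes.
#' @examples
#' haldanes(3.85, 2.916, 35, 4.67)  # 0.176
#' @export
haldanes <- function(delta_mm, pooled_sd_mm, span_years,
                     generation_time_years) {
  if (pooled_sd_mm <= 0) stop("pooled_sd_mm must be > 0", call. = FALSE)
  if (span_years <= 0) stop("span_years must be > 0", call. = FALSE)
  if (generation_time_years <= 0)
    stop("generation_time_years must be > 0", call. = FALSE)
  (delta_mm / pooled_sd_mm) / (span_years / generation_time_years)
}

#' Rate of phenotypic change in darwins
#'
#' Proportional change per million years. Two conventions are provided:
#' `"log_ratio"`, `|ln(start) - ln(start + delta)| / (span * 1e-6)`, and
#' `"proportional"`, `(|delta| / start) / (span * 1e-6)`. They agree to first
#' order for small relative changes; the proportional form is the package
#' default.
#'
#' @param start_mm reference (starting) trait value (mm, > 0).
#' @param delta_mm total change (mm, signed; `|delta| < start`).
#' @param span_years elapsed time (years, > 0).
#' @param formula `"proportional"` or `"log_ratio"`.
#' @return rate in darwins (magnitude).
#' @examples
#' darwins(100.2, -3.85, 35)  # about 1098
#' @export
darwins <- function(start_mm, delta_mm, span_years,
                    formula = c("proportional", "log_ratio")) {
  formula <- match.arg(formula)
  if (start_mm <= 0) stop("start_mm must be > 0", call. = FALSE)
  if (span_years <= 0) stop("span_years must be > 0", call. = FALSE)
  if (abs(delta_mm) >= start_mm)
    stop("|delta_mm| must be smaller than start_mm", call. = FALSE)
  span_myr <- span_years * 1e-6
  switch(formula,
         proportional = (abs(delta_mm) / start_mm) / span_myr,
         log_ratio = abs(log(start_mm) - log(start_mm + delta_mm)) / span_myr)
}

#' Bundle both evolutionary rates with their inputs
#'
#' @param delta_mm total change (mm, signed).
#' @param start_mm reference trait value (mm).
#' @param span_years elapsed time in years.
#' @param pooled_sd_mm pooled phenotypic SD (mm); the packaged default is the
#'   breeding-population wing-length value 2.916 mm.
#' @param generation_time_years generation time; the packaged default is the
#'   demographic estimate 4.67 years.
#' @param darwin_formula `"proportional"` (default) or `"log_ratio"`.
#' @return a list of class `rate_estimate` holding `darwins`, `haldanes` and
#'   every input.
#' @examples
#' rate_estimate(delta_mm = -3.85, start_mm = 100.2, span_years = 35)
#' @export
rate_estimate <- function(delta_mm, start_mm, span_years,
                          pooled_sd_mm = 2.916,
                          generation_time_years = 4.67,
                          darwin_formula = c("proportional", "log_ratio")) {
  darwin_formula <- match.arg(darwin_formula)
  structure(list(
    darwins = darwins(start_mm, delta_mm, span_years, darwin_formula),
    haldanes = haldanes(delta_mm, pooled_sd_mm, span_years,
                        generation_time_years),
    delta_mm = delta_mm, start_mm = start_mm, span_years = span_years,
    pooled_sd_mm = pooled_sd_mm,
    generation_time_years = generation_time_years,
    darwin_formula = darwin_formula),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate of phenotypic change over %g years:\n", x$span_years))
  cat(sprintf("  %.0f darwins (%s formula, reference %.2f mm)\n",
              x$darwins, x$darwin_formula, x$start_mm))
  cat(sprintf("  %.3f haldanes (pooled SD %.3f mm, generation time %.2f yr)\n",
              x$haldanes, x$pooled_sd_mm, x$generation_time_years))
  invisible(x)
}

#' Predicted correlated change in a second trait
#'
#' Given the allometric slope of trait B on trait A (mm per mm) and an
#' observed change in A, the change in B expected from the phenotypic
#' covariance alone.
#'
#' @param allometric_slope slope of B on A (dimensionless).
#' @param delta_a_mm observed change in trait A (mm, signed).
#' @return predicted change in trait B (mm, signed).
#' @examples
#' predicted_correlated_change(0.223, -3.85)
#' @export
predicted_correlated_change <- function(allometric_slope, delta_a_mm) {
  allometric_slope * delta_a_mm
}
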