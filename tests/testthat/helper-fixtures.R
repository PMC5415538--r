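# Small in-code builders used across the test files.

make_annual <- function(years, means, site_id = "s1", region = "central",
                        metric = "wing", method = "flattened",
                        se = rep(0.1, length(years)),
                        n = rep(30L, length(years)),
                        trend_eligible = TRUE) {
  out <- data.frame(
    site_id = site_id, region = region, year = as.integer(years),
    metric = metric, method = method, mean_mm = means,
    se_mm = se, n = as.integer(n), trend_eligible = trend_eligible,
    exclusion_reason = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("annual_table", "data.frame")
  out
}

make_records <- function(wing, culmen = NA_real_, site_id = "s1",
                         region = "central", year = 2000L, sex = "unknown",
                         method = "flattened", source = "live") {
  k <- max(length(wing), length(culmen))
  data.frame(
    record_id = sprintf("r%03d", seq_len(k)), site_id = site_id,
    region = region, year = as.integer(year), sex = sex,
    wing_mm = rep_len(wing, k), culmen_mm = rep_len(culmen, k),
    method = method, source = source, shrinkage_applied = FALSE,
    stringsAsFactors = FALSE)
}

# breeding-region wing subset used by several trend tests
breeding_wing <- function(tbl = sandpiper_annual()) {
  trend_subset(tbl, "wing", region = c("west", "central", "east"))
}
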