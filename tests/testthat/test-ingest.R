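test_that("packaged annual table reads with fields and flags intact", {
  tbl <- sandpiper_annual()
  jb75 <- tbl[tbl$site_id == "james_bay" & tbl$year == 1975 &
                tbl$metric == "wing", ]
  expect_equal(jb75$mean_mm, 98.75)
  expect_equal(jb75$se_mm, 0.05)
  expect_equal(jb75$n, 2202L)
  expect_true(jb75$trend_eligible)

  f98 <- tbl[tbl$site_id == "fundy" & tbl$year == 1998 &
               tbl$metric == "wing", ]
  expect_false(f98$trend_eligible)
  expect_match(f98$exclusion_reason, "measurement techniques")
  expect_identical(f98$method, "mixed_unknown")

  # mixed/unknown-method wing rows are never trend-eligible
  expect_true(all(!tbl$trend_eligible[tbl$metric == "wing" &
                                        tbl$method == "mixed_unknown"]))
})

test_that("reading handles empty, malformed and renamed inputs", {
  hdr <- "site_id,region,year,metric,method,mean_mm,se_mm,n,trend_eligible,exclusion_reason"
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(hdr, f)
  expect_equal(nrow(read_annual_table(f)), 0L)

  writeLines(c(hdr, "a,west,1990,wing,flattened,not_a_number,0.1,10,TRUE,"), f)
  expect_error(read_annual_table(f), "non-numeric 'mean_mm' in row\\(s\\) 1")

  writeLines("site_id,region,year", f)
  expect_error(read_annual_table(f), "missing column.*metric")

  # schema remapping of a renamed column
  writeLines(c(sub("mean_mm", "avg", hdr),
               "a,west,1990,wing,flattened,95.5,0.1,10,TRUE,"), f)
  tbl <- read_annual_table(f, schema = c(mean_mm = "avg"))
  expect_equal(tbl$mean_mm, 95.5)
})

test_that("write/read round-trips the packaged table exactly", {
  tbl <- sandpiper_annual()
  f <- withr::local_tempfile(fileext = ".csv")
  write_annual_table(tbl, f)
  back <- read_annual_table(f)
  expect_identical(as.data.frame(back), as.data.frame(tbl))
})

test_that("shrinkage correction scales wings 2% and culmens 1%, once only", {
  rec <- make_records(wing = 95, culmen = 20, source = "museum")
  out <- shrinkage_correct(rec)
  expect_equal(out$wing_mm, 96.90)
  expect_equal(out$culmen_mm, 20.20)
  expect_true(all(out$shrinkage_applied))
  expect_error(shrinkage_correct(out), "already been applied")
  expect_error(shrinkage_correct(make_records(wing = 95, source = "live")),
               "museum")
  bad <- make_records(wing = 0, culmen = 20, source = "museum")
  expect_error(shrinkage_correct(bad), "positive")
})

test_that("narina-to-culmen conversion follows the calibration line", {
  expect_equal(narina_to_culmen(18), 19.80)
  expect_equal(narina_to_culmen(10), 11.48)
  expect_error(narina_to_culmen(0), "positive")
  expect_error(narina_to_culmen(-3), "positive")
})

test_that("annual summaries use sample SD over sqrt(n) and refuse mixed methods", {
  rec <- make_records(wing = c(98, 100, 102))
  s <- summarize_annual(rec, "s1", 2000, "wing")
  expect_equal(s$mean_mm, 100)
  expect_equal(s$se_mm, 2 / sqrt(3), tolerance = 1e-10)
  expect_equal(s$n, 3L)

  s0 <- summarize_annual(make_records(wing = c(97, 97, 97)), "s1", 2000, "wing")
  expect_equal(s0$mean_mm, 97)
  expect_equal(s0$se_mm, 0)

  mixed <- rbind(make_records(wing = c(98, 99)),
                 make_records(wing = c(96, 97), method = "natural_chord"))
  mixed$record_id <- sprintf("r%03d", seq_len(nrow(mixed)))
  expect_error(summarize_annual(mixed, "s1", 2000, "wing"),
               "mixed measurement methods")
  expect_error(summarize_annual(make_records(wing = 98), "s1", 2000, "wing"),
               "at least 2")
})

test_that("weighted pooling matches hand arithmetic and identities", {
  jb <- make_annual(c(2014, 2015), c(97.10, 98.36), se = c(0.17, 0.24),
                    n = c(227L, 104L))
  p <- pool_weighted(jb)
  expect_equal(p$mean_mm, (227 * 97.10 + 104 * 98.36) / 331, tolerance = 1e-10)
  expect_equal(round(p$mean_mm, 2), 97.50)

  one <- make_annual(2000, 98.5, se = 0.2, n = 50L)
  p1 <- pool_weighted(one)
  expect_equal(p1$mean_mm, 98.5)
  expect_equal(p1$n, 50L)
  expect_equal(p1$se_mm, 0.2, tolerance = 1e-10)  # identity on one sample

  two <- make_annual(c(2000, 2001), c(96, 100), n = c(40L, 40L))
  expect_equal(pool_weighted(two)$mean_mm, 98)

  expect_error(pool_weighted(jb[0, ]), "empty")
  both <- rbind(make_annual(2000, 98, metric = "wing"),
                make_annual(2000, 20, metric = "culmen"))
  expect_error(pool_weighted(both), "across metrics")
})

test_that("pooling annual summaries equals summarizing the concatenated records", {
  set.seed(11)
  y1 <- rnorm(25, 98, 2); y2 <- rnorm(40, 97, 2.5); y3 <- rnorm(12, 99, 1.5)
  recs <- rbind(make_records(y1, year = 2001),
                make_records(y2, year = 2002),
                make_records(y3, year = 2003))
  recs$record_id <- sprintf("r%03d", seq_len(nrow(recs)))
  summ <- rbind(summarize_annual(recs, "s1", 2001, "wing"),
                summarize_annual(recs, "s1", 2002, "wing"),
                summarize_annual(recs, "s1", 2003, "wing"))
  p <- pool_weighted(summ)
  all_vals <- c(y1, y2, y3)
  expect_equal(p$mean_mm, mean(all_vals), tolerance = 1e-12)
  expect_equal(p$sd_mm, sd(all_vals), tolerance = 1e-12)
  expect_equal(p$n, length(all_vals))
})
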