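published_row <- function() {
  data.frame(term = "ARIA-E", a = 141, ror_low = 42177.8, prr = 46644.4,
             chi2 = 3390009, ic_minus_2sd = 6.83, ebgm05 = 18942.0)
}

test_that("joint criteria require all five conditions", {
  d <- evaluate_criteria(published_row())
  expect_true(d$significant)

  # a count of 2 vetoes arbitrarily strong statistics
  low <- published_row()
  low$a <- 2
  expect_false(evaluate_criteria(low)$significant)

  # undefined statistics fail their criterion
  nas <- published_row()
  nas$ic_minus_2sd <- NA_real_
  expect_false(evaluate_criteria(nas)$significant)
})

test_that("threshold boundaries follow the stated strict/weak semantics", {
  edge <- data.frame(term = "edge", a = 3, ror_low = 1.0, prr = 2.0,
                     chi2 = 4.0, ic_minus_2sd = 0.0, ebgm05 = 2.0)
  d <- evaluate_criteria(edge)
  expect_true(d$count_ok)    # >= 3 passes at 3
  expect_true(d$prr_ok)      # >= 2 with chi2 >= 4 passes at the boundary
  expect_false(d$ror_ok)     # strict > 1 fails at exactly 1
  expect_false(d$ic_ok)      # strict > 0 fails at exactly 0
  expect_false(d$ebgm_ok)    # strict > 2 fails at exactly 2
  expect_false(d$significant)
})

test_that("raising the count never demotes a significant term", {
  base <- published_row()
  for (a in c(3, 10, 141, 1000)) {
    base$a <- a
    expect_true(evaluate_criteria(base)$significant)
  }
})

make_set <- function(seed = 5, implant = NULL, n_bg = 3000, n_fc = 400) {
  voc <- default_vocabulary()
  cfg <- synthetic_config(
    n_background_reports = n_bg, n_focal_reports = n_fc,
    pt_vocabulary = voc,
    implanted_rr = implant %||% setNames(8, "Confusional state"),
    duplicate_rate = 0, seed = seed
  )
  d <- generate_faers(cfg)
  prepare_analysis(d, "aducanumab", pt_soc_map = synthetic_pt_soc_map())
}

test_that("stratified margins partition the unstratified table", {
  set <- make_set()
  full <- build_contingency(set$reactions, set$focal_ids, unit = "event")
  strata <- list(stratum_spec("female", sex = "female"),
                 stratum_spec("male", sex = "male"),
                 stratum_spec("unknown", sex = "unknown"))
  res <- run_stratified(set, strata, unit = "event",
                        ic_estimator = "gamma", prior = mgps_prior())
  agg <- tapply(res$a, res$term, sum)
  for (t in full$term) {
    expect_equal(unname(agg[[t]]), full$a[full$term == t])
  }
  expect_true(all(res$low_count == (res$a < 3)))
})

test_that("an all-inclusive stratum reproduces the unstratified analysis", {
  set <- make_set(seed = 6)
  yrs <- range(set$records$report_year, na.rm = TRUE)
  res <- run_stratified(set, list(stratum_spec("all", period = yrs)),
                        unit = "event", ic_estimator = "gamma",
                        prior = mgps_prior())
  full <- signal_stats(build_contingency(set$reactions, set$focal_ids,
                                         unit = "event"),
                       prior = mgps_prior(), ic_estimator = "gamma")
  expect_equal(res$a, full$a)
  expect_equal(res$ror, full$ror)
  expect_equal(res$ebgm, full$ebgm)
})

test_that("empty strata warn and contribute nothing", {
  set <- make_set(seed = 7)
  expect_warning(
    res <- run_stratified(set, list(stratum_spec("none", sex = "nonesuch")),
                          ic_estimator = "gamma", prior = mgps_prior()),
    "matches no records")
  expect_equal(nrow(res), 0L)
})

test_that("a shared implanted effect yields overlapping sex-stratified CIs", {
  # same relative risk planted in both sexes: intervals should overlap
  overlaps <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    set <- make_set(seed = 100 + s,
                    implant = setNames(10, "Confusional state"))
    res <- run_stratified(
      set, list(stratum_spec("female", sex = "female"),
                stratum_spec("male", sex = "male")),
      unit = "event", ic_estimator = "gamma", prior = mgps_prior())
    r <- res[res$term == "Confusional state", ]
    if (nrow(r) == 2 && all(is.finite(r$ror_low))) {
      if (max(r$ror_low) <= min(r$ror_high)) overlaps <- overlaps + 1L
    }
  }
  expect_gte(overlaps, n_rep - 2L)
})

test_that("cumulative temporal analysis accumulates and ends at the full data", {
  set <- make_set(seed = 8)
  yrs <- sort(unique(set$records$report_year))
  tm <- run_temporal(set, yrs, unit = "event", ic_estimator = "gamma")
  full <- build_contingency(set$reactions, set$focal_ids, unit = "event")
  ic_full <- compute_bcpnn_ic(full$a, full$b, full$c, full$d,
                              estimator = "gamma")
  last <- tm$ic[, ncol(tm$ic)]
  for (t in full$term[full$a > 0]) {
    expect_equal(unname(last[t]), ic_full$ic[full$term == t])
  }
  # a period edge before any report yields only missing markers
  tm0 <- run_temporal(set, c(min(yrs) - 5, yrs), unit = "event",
                      ic_estimator = "gamma")
  expect_true(all(is.na(tm0$ic[, 1])))
  # all reports in one year: every later period identical
  one <- set
  one$records$report_year <- 2022L
  one$reactions$report_year <- 2022L
  tm1 <- run_temporal(one, c(2022, 2023, 2024), unit = "event",
                      ic_estimator = "gamma")
  expect_equal(tm1$ic[, "2022"], tm1$ic[, "2024"])
  expect_error(run_temporal(set, c(2024, 2022)), class = "faers_config_error")
})

test_that("a doubling report stream gives non-decreasing cumulative IC", {
  # direct construction: the focal share of term X doubles each year against
  # a large, compositionally stable background
  yrs <- 2018:2022
  per_year <- function(i) {
    yr <- yrs[i]
    c(rep(list(c("F", "X", yr)), 2^i),        # X doubles each year
      rep(list(c("F", "O", yr)), 20),          # flat focal background
      rep(list(c("B", "X", yr)), 100),
      rep(list(c("B", "Y", yr)), 950),
      rep(list(c("B", "Z", yr)), 950))
  }
  rows <- do.call(rbind, lapply(unlist(lapply(seq_along(yrs), per_year),
                                       recursive = FALSE), rbind))
  reac <- data.frame(
    case_id = paste0(rows[, 1], seq_len(nrow(rows))),
    pt = rows[, 2],
    report_year = as.integer(rows[, 3]),
    sex = "female", age_group = "65-74", serious = "serious",
    stringsAsFactors = FALSE
  )
  records <- data.frame(case_id = reac$case_id,
                        report_year = reac$report_year,
                        sex = "female", age_group = "65-74",
                        serious = "serious",
                        focal = grepl("^F", reac$case_id),
                        stringsAsFactors = FALSE)
  set <- structure(list(records = records, reactions = reac,
                        focal_ids = records$case_id[records$focal],
                        pt_soc_map = NULL),
                   class = "faers_analysis_set")
  tm <- run_temporal(set, yrs, unit = "event", ic_estimator = "gamma")
  ic_x <- tm$ic["X", ]
  expect_true(all(is.finite(ic_x)))
  expect_true(all(diff(ic_x) >= -1e-9))
})

test_that("onset summaries use type-7 quantiles and inclusive bins", {
  s <- compute_onset(c(1, 2, 3))
  expect_equal(s$median_days, 2)

  s2 <- compute_onset(c(15, 45, 400))
  expect_equal(unname(s2$bin_counts[c("0-30", "31-60", ">360")]),
               c(1L, 1L, 1L))
  expect_equal(sum(s2$bin_counts), s2$n)

  # inclusive endpoints and day zero; negatives excluded but counted
  s3 <- compute_onset(c(0, 30, 31, 60, 360, 361, -5, NA))
  expect_equal(unname(s3$bin_counts["0-30"]), 2L)
  expect_equal(unname(s3$bin_counts["31-60"]), 2L)
  expect_equal(unname(s3$bin_counts["181-360"]), 1L)
  expect_equal(unname(s3$bin_counts[">360"]), 1L)
  expect_equal(s3$n_negative, 1L)
  expect_equal(s3$n_missing, 1L)
  expect_equal(quantile(c(0, 30, 31, 60, 360, 361), 0.5, type = 7,
                        names = FALSE), s3$median_days)
})

test_that("demographic summary reproduces hand-computed percentages", {
  rec <- expand_demographic_records()
  dem <- summarize_demographics(rec)
  cats <- dem$categories
  g <- function(cat, lv) cats[cats$category == cat & cats$level == lv, ]
  expect_equal(g("sex", "female")$pct, 49.80)
  expect_equal(g("sex", "male")$pct, 44.51)
  expect_equal(g("sex", "unknown")$pct, 5.69)
  expect_equal(g("country", "United States")$n, 473L)

  # single-record dataset: 100% in its categories
  one <- rec[1, ]
  d1 <- summarize_demographics(one)
  expect_equal(d1$categories$pct[d1$categories$category == "sex" &
                                   d1$categories$n > 0], 100)

  # planted fixture percentages match direct division to 2 decimals
  set.seed(31)
  n <- 510
  plant <- rec
  plant$reporter <- sample(c("consumer", "physician"), n, TRUE, c(.7, .3))
  d2 <- summarize_demographics(plant)
  rc <- d2$categories[d2$categories$category == "reporter", ]
  expect_equal(rc$pct[rc$level == "consumer"],
               round(100 * sum(plant$reporter == "consumer") / n, 2))
})
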