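#' Configure an end-to-end analysis run
#'
#' @param input Either a named list of paths (`demo`, `drug`, `reac`,
#'   optionally `ther`) or a [synthetic_config()] to generate the data.
#' @param dictionary Focal-drug name patterns.
#' @param roles Drug role codes defining exposure.
#' @param pt_soc_map A PT-to-SOC map `data.frame`, a CSV path, or `NULL` to
#'   use the bundled synthetic vocabulary.
#' @param pt_unit,soc_unit Counting units for the PT and SOC level tables.
#'   Event counting is the PT-level default, report counting the SOC-level
#'   default.
#' @param ic_estimator,n_draws IC lower-bound estimator settings.
#' @param criteria Named list overriding [evaluate_criteria()] thresholds.
#' @param strata List of [stratum_spec()]; `NULL` selects the standard
#'   sex and age-group strata.
#' @param period_edges Years for the cumulative temporal analysis; `NULL`
#'   derives them from the data.
#' @param out_dir Artifact directory.
#' @param seed Root seed for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(input, dictionary, roles = "PS", pt_soc_map = NULL,
                       pt_unit = "event", soc_unit = "report",
                       ic_estimator = "mc", n_draws = 1e5,
                       criteria = list(), strata = NULL, period_edges = NULL,
                       out_dir = tempfile("faersignal_run_"), seed = 1L) {
  if (!ic_estimator %in% c("mc", "gamma")) {
    stop_faers("unknown ic_estimator: '", ic_estimator,
               "' (use 'mc' or 'gamma')", class = "faers_config_error")
  }
  if (is.list(input) && !inherits(input, "synthetic_config")) {
    for (p in unlist(input)) {
      if (!file.exists(p)) {
        stop_faers("input path does not exist: ", p, class = "faers_io_error")
      }
    }
  }
  bad <- unlist(criteria) <= 0 & names(unlist(criteria)) != "ic2sd_gt"
  if (length(bad) && any(bad)) {
    stop_faers("criteria thresholds must be positive",
               class = "faers_config_error")
  }
  structure(list(input = input, dictionary = dictionary, roles = roles,
                 pt_soc_map = pt_soc_map, pt_unit = pt_unit,
                 soc_unit = soc_unit, ic_estimator = ic_estimator,
                 n_draws = n_draws, criteria = criteria, strata = strata,
                 period_edges = period_edges, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

default_strata <- function(set) {
  groups <- intersect(c("45-64", "65-74", ">=75"),
                      unique(set$records$age_group))
  c(list(stratum_spec("female", sex = "female"),
         stratum_spec("male", sex = "male")),
    lapply(groups, function(g) stratum_spec(paste0("age_", g),
                                            age_group = g)),
    list(stratum_spec("serious", serious = "serious"),
         stratum_spec("non-serious", serious = "non-serious")))
}

#' Run the full signal-detection analysis and export its artifacts
#'
#' Orchestrates ingestion (or synthesis), deduplication, focal-drug
#' filtering, PT- and SOC-level contingency tables, the four-method
#' statistics panel, the joint signal criteria, demographic summary,
#' stratified and cumulative temporal analyses, and the time-to-onset
#' summary. Writes all products plus a run manifest to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every computed product and
#'   `artifacts` (named file paths).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  data <- if (inherits(config$input, "synthetic_config")) {
    generate_faers(config$input)
  } else {
    read_faers_data(config$input$demo, config$input$drug, config$input$reac,
                    config$input$ther)
  }
  map <- config$pt_soc_map
  if (is.null(map)) map <- synthetic_pt_soc_map()
  if (is.character(map)) map <- read_pt_soc_map(map)

  counts <- list(demo = nrow(data$demo), drug = nrow(data$drug),
                 reac = nrow(data$reac))
  set <- prepare_analysis(data, config$dictionary, config$roles, map)
  counts$cases <- nrow(set$records)
  counts$focal_cases <- length(set$focal_ids)
  counts$events <- nrow(set$reactions)
  message(sprintf("ingest: %d demo / %d drug / %d reac records -> %d cases (%d focal, %d events)",
                  counts$demo, counts$drug, counts$reac, counts$cases,
                  counts$focal_cases, counts$events))

  stat_seed <- substream_seed(config$seed, "disprop")
  tab_pt <- build_contingency(set$reactions, set$focal_ids, "PT",
                              unit = config$pt_unit)
  st_pt <- signal_stats(tab_pt, ic_estimator = config$ic_estimator,
                        n_draws = config$n_draws, seed = stat_seed)
  tab_soc <- build_contingency(set$reactions, set$focal_ids, "SOC",
                               pt_soc_map = map, unit = config$soc_unit)
  st_soc <- signal_stats(tab_soc, ic_estimator = config$ic_estimator,
                         n_draws = config$n_draws, seed = stat_seed + 1)
  dec <- do.call(evaluate_criteria, c(list(st_pt), config$criteria))

  demog <- summarize_demographics(set)
  strata <- config$strata %||% default_strata(set)
  strat <- run_stratified(set, strata, level = "PT", unit = config$pt_unit,
                          ic_estimator = config$ic_estimator,
                          n_draws = config$n_draws,
                          seed = substream_seed(config$seed, "strata"))
  yrs <- config$period_edges %||%
    sort(unique(set$records$report_year[set$records$focal]))
  temporal <- run_temporal(set, yrs, level = "PT", unit = config$pt_unit,
                           ic_estimator = config$ic_estimator,
                           n_draws = config$n_draws,
                           seed = substream_seed(config$seed, "temporal"))
  onset <- compute_onset(set)

  od <- config$out_dir
  art <- c(
    statistics_pt = file.path(od, "statistics_pt.csv"),
    statistics_soc = file.path(od, "statistics_soc.csv"),
    decisions = file.path(od, "decisions.csv"),
    demographics = file.path(od, "demographics.csv"),
    stratified = file.path(od, "stratified_forest.csv"),
    temporal = file.path(od, "temporal_ic.csv"),
    onset = file.path(od, "onset.json"),
    manifest = file.path(od, "manifest.json")
  )
  wcsv <- function(x, p) utils::write.csv(x, p, row.names = FALSE, na = "")
  wcsv(st_pt, art["statistics_pt"])
  wcsv(st_soc, art["statistics_soc"])
  wcsv(dec, art["decisions"])
  wcsv(demog$categories, art["demographics"])
  forest <- strat[, intersect(c("stratum", "term", "a", "ror", "ror_low",
                                "ror_high", "low_count"), names(strat))]
  wcsv(forest, art["stratified"])
  tm <- data.frame(term = rownames(temporal$ic), temporal$ic,
                   check.names = FALSE)
  wcsv(tm, art["temporal"])
  jsonlite::write_json(
    list(n = onset$n, median_days = onset$median_days,
         q1_days = onset$q1_days, q3_days = onset$q3_days,
         bin_counts = as.list(onset$bin_counts),
         n_negative = onset$n_negative, n_missing = onset$n_missing),
    art["onset"], auto_unbox = TRUE, digits = NA)

  cfg_json <- jsonlite::toJSON(config_manifest(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    config = jsonlite::fromJSON(cfg_json),
    record_counts = counts,
    criteria = config$criteria,
    n_significant = sum(dec$significant)
  )
  unlink(tmp)
  jsonlite::write_json(manifest, art["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(set = set, statistics_pt = st_pt, statistics_soc = st_soc,
                 decisions = dec, demographics = demog, stratified = strat,
                 temporal = temporal, onset = onset, artifacts = art,
                 counts = counts))
}

# JSON-serialisable view of a run_config (paths or synthetic parameters).
config_manifest <- function(config) {
  inp <- if (inherits(config$input, "synthetic_config")) {
    c(unclass(config$input)[c("n_background_reports", "n_focal_reports",
                              "duplicate_rate", "seed")],
      list(type = "synthetic", n_pts = nrow(config$input$pt_vocabulary),
           implanted_rr = as.list(config$input$implanted_rr)))
  } else {
    c(list(type = "files"), config$input)
  }
  list(input = inp, dictionary = config$dictionary, roles = config$roles,
       pt_unit = config$pt_unit, soc_unit = config$soc_unit,
       ic_estimator = config$ic_estimator, n_draws = config$n_draws,
       seed = config$seed)
}

#' Recompute statistics from published (count, ROR) rows
#'
#' Reconstructs each 2x2 table from a published case count and reporting odds
#' ratio given the focal-drug and database event margins, then recomputes the
#' deterministic statistics panel (ROR with CI, PRR, chi-square, IC with the
#' closed-form gamma lower bound, observed/expected ratio) and applies the
#' joint criteria's frequentist subset. Rows whose reconstruction is
#' infeasible (`ror <= 0`, or background cell rounding to zero) are flagged
#' and skipped, not fatal.
#'
#' @param x `data.frame` with columns `term`, `n` (the case count) and `ror`,
#'   or a path to such a CSV.
#' @param drug_total,grand_total Event margins (`a + b` and `N`).
#' @param prior Optional [mgps_prior()]; when supplied, EBGM and EBGM05 are
#'   added.
#' @return `data.frame`: `term`, `feasible`, the reconstructed cells and the
#'   recomputed statistics, plus logical criteria columns `count_ok`,
#'   `ror_ok`, `prr_ok` and `frequentist_signal`.
#' @export
reconstruct_published <- function(x, drug_total, grand_total, prior = NULL) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  if (!all(c("term", "n", "ror") %in% names(x))) {
    stop_faers("need columns term, n, ror", class = "faers_schema_error")
  }
  ok <- x$ror > 0 & x$n >= 1 & x$n <= drug_total
  out <- data.frame(term = x$term, n = x$n, ror_input = x$ror,
                    feasible = ok, a = NA_real_, b = NA_real_, c = NA_real_,
                    d = NA_real_, stringsAsFactors = FALSE)
  if (any(ok)) {
    rec <- reconstruct_contingency(x$n[ok], x$ror[ok], drug_total,
                                   grand_total, flag_infeasible = TRUE)
    out[ok, c("a", "b", "c", "d")] <- rec[, c("a", "b", "c", "d")]
    out$feasible[ok] <- rec$feasible
  }
  f <- out$feasible & !is.na(out$a)
  out$ror <- out$ror_low <- out$ror_high <- out$prr <- out$chi2 <-
    out$ic <- out$ic_minus_2sd <- out$rr <- NA_real_
  if (any(f)) {
    a <- out$a[f]; b <- out$b[f]; c <- out$c[f]; d <- out$d[f]
    N <- a + b + c + d
    E <- (a + b) * (a + c) / N
    out[f, c("ror", "ror_low", "ror_high")] <- compute_ror(a, b, c, d)
    out[f, c("prr", "chi2")] <- compute_prr_chi2(a, b, c, d)
    ic <- compute_bcpnn_ic(a, b, c, d, estimator = "gamma")
    out$ic[f] <- ic$ic
    out$ic_minus_2sd[f] <- ic$ic_minus_2sd
    out$rr[f] <- a / E
    if (!is.null(prior)) {
      out$ebgm <- out$ebgm05 <- NA_real_
      out[f, c("ebgm", "ebgm05")] <- compute_ebgm(a, E, prior)[, 1:2]
    }
  }
  out$count_ok <- !is.na(out$a) & out$a >= 3
  out$ror_ok <- !is.na(out$ror_low) & out$ror_low > 1
  out$prr_ok <- !is.na(out$prr) & out$prr >= 2 & !is.na(out$chi2) &
    out$chi2 >= 4
  out$frequentist_signal <- out$count_ok & out$ror_ok & out$prr_ok
  out
}
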