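#' Joint signal criteria
#'
#' A drug-event pair is flagged as a significant safety signal when it meets
#' all five conditions simultaneously: case count `a >= 3`, lower bound of the
#' ROR 95% CI `> 1`, `PRR >= 2` with `chi2 >= 4`, `IC - 2SD > 0`, and
#' `EBGM05 > 2`. The comparison operators are applied exactly as stated
#' (weak inequalities for count, PRR and chi-square; strict for the three
#' interval bounds), so a statistic sitting exactly on a strict threshold does
#' not pass. Undefined (`NA`) statistics fail their criterion.
#'
#' @param stats A statistics `data.frame` from [signal_stats()] (needs `term`,
#'   `a`, `ror_low`, `prr`, `chi2`, `ic_minus_2sd`, `ebgm05`).
#' @param min_count,ror_low_gt,prr_ge,chi2_ge,ic2sd_gt,ebgm05_gt Thresholds;
#'   defaults are the standard joint criteria.
#' @return The input with logical columns `count_ok`, `ror_ok`, `prr_ok`,
#'   `ic_ok`, `ebgm_ok` and `significant`.
#' @export
evaluate_criteria <- function(stats, min_count = 3, ror_low_gt = 1,
                              prr_ge = 2, chi2_ge = 4, ic2sd_gt = 0,
                              ebgm05_gt = 2) {
  need <- c("a", "ror_low", "prr", "chi2", "ic_minus_2sd", "ebgm05")
  miss <- setdiff(need, names(stats))
  if (length(miss)) {
    stop_faers("missing statistics columns: ", paste(miss, collapse = ", "),
               class = "faers_value_error")
  }
  ok <- function(x) !is.na(x) & x
  stats$count_ok <- ok(stats$a >= min_count)
  stats$ror_ok <- ok(stats$ror_low > ror_low_gt)
  stats$prr_ok <- ok(stats$prr >= prr_ge) & ok(stats$chi2 >= chi2_ge)
  stats$ic_ok <- ok(stats$ic_minus_2sd > ic2sd_gt)
  stats$ebgm_ok <- ok(stats$ebgm05 > ebgm05_gt)
  stats$significant <- stats$count_ok & stats$ror_ok & stats$prr_ok &
    stats$ic_ok & stats$ebgm_ok
  stats
}

#' Specify an analysis stratum
#'
#' @param name Label for the stratum.
#' @param sex,age_group,serious Category filters (character vectors) or `NULL`.
#' @param period `c(start_year, end_year)` or `NULL`.
#' @return A `stratum_spec` list. At least one filter must be set.
#' @export
stratum_spec <- function(name, sex = NULL, age_group = NULL, period = NULL,
                         serious = NULL) {
  if (is.null(sex) && is.null(age_group) && is.null(period) &&
      is.null(serious)) {
    stop_faers("a stratum needs at least one filter", class = "faers_config_error")
  }
  structure(list(name = name, sex = sex, age_group = age_group,
                 period = period, serious = serious),
            class = "stratum_spec")
}

#' Stratified disproportionality analysis
#'
#' Re-runs table building and the statistics panel within each stratum. Both
#' the focal and the comparator margins are restricted to the stratum, the
#' standard subgroup-disproportionality convention that removes stratum-level
#' confounding. Terms with fewer than 3 focal cases in a stratum are retained
#' but flagged `low_count`.
#'
#' @param set A `faers_analysis_set`.
#' @param strata A list of [stratum_spec()] objects.
#' @param level,unit,pt_soc_map As in [build_contingency()].
#' @param ... Passed to [signal_stats()].
#' @return One `data.frame` with a leading `stratum` column; empty strata
#'   contribute no rows and raise a warning.
#' @export
run_stratified <- function(set, strata, level = "PT", unit = "event",
                           pt_soc_map = NULL, ...) {
  stopifnot(inherits(set, "faers_analysis_set"))
  out <- list()
  for (sp in strata) {
    stopifnot(inherits(sp, "stratum_spec"))
    sub <- subset_analysis_set(set, sex = sp$sex, age_group = sp$age_group,
                               period = sp$period, serious = sp$serious)
    if (nrow(sub$reactions) == 0L || length(sub$focal_ids) == 0L) {
      warning(sprintf("stratum '%s' matches no records", sp$name),
              call. = FALSE)
      next
    }
    tab <- build_contingency(sub$reactions, sub$focal_ids, level = level,
                             pt_soc_map = pt_soc_map, unit = unit)
    st <- signal_stats(tab, ...)
    st$low_count <- st$a < 3
    st <- cbind(stratum = sp$name, st, stringsAsFactors = FALSE)
    out[[sp$name]] <- st
  }
  if (length(out) == 0L) {
    return(data.frame(stratum = character(0), term = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative temporal signal analysis
#'
#' For each period end-year, recomputes the information component on all
#' reports received up to and including that year (cumulative convention, the
#' natural reading of progressively accumulating safety signals). Cells where
#' a term has no focal report yet are `NA`.
#'
#' @param set A `faers_analysis_set`.
#' @param period_edges Ascending integer years marking period ends.
#' @param level,unit,pt_soc_map As in [build_contingency()].
#' @param cumulative If `FALSE`, each period counts only its own years
#'   (non-cumulative variant).
#' @param ic_estimator,n_draws,seed Passed to [compute_bcpnn_ic()].
#' @return A `faers_temporal` object: list of matrices `ic` and
#'   `ic_minus_2sd` (terms x periods) and the `a` count matrix.
#' @export
run_temporal <- function(set, period_edges, level = "PT", unit = "event",
                         pt_soc_map = NULL, cumulative = TRUE,
                         ic_estimator = "mc", n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(set, "faers_analysis_set"))
  if (is.unsorted(period_edges, strictly = TRUE)) {
    stop_faers("period_edges must be strictly ascending",
               class = "faers_config_error")
  }
  full <- build_contingency(set$reactions, set$focal_ids, level = level,
                            pt_soc_map = pt_soc_map, unit = unit)
  terms <- full$term
  np <- length(period_edges)
  mk <- function() matrix(NA_real_, nrow = length(terms), ncol = np,
                          dimnames = list(terms, period_edges))
  ic_m <- mk(); lo_m <- mk(); a_m <- mk()
  prev_start <- -Inf
  for (j in seq_len(np)) {
    start <- if (cumulative) -Inf else prev_start
    sub <- subset_analysis_set(set, period = c(max(start, 0),
                                               period_edges[j]))
    prev_start <- period_edges[j] + 1
    if (nrow(sub$reactions) == 0L || length(sub$focal_ids) == 0L) next
    tab <- build_contingency(sub$reactions, sub$focal_ids, level = level,
                             pt_soc_map = pt_soc_map, unit = unit)
    ic <- compute_bcpnn_ic(tab$a, tab$b, tab$c, tab$d,
                           estimator = ic_estimator, n_draws = n_draws,
                           seed = if (!is.null(seed)) seed + j)
    idx <- match(tab$term, terms)
    keep <- !is.na(idx) & tab$a > 0
    ic_m[idx[keep], j] <- ic$ic[keep]
    lo_m[idx[keep], j] <- ic$ic_minus_2sd[keep]
    a_m[idx[keep], j] <- tab$a[keep]
  }
  structure(list(ic = ic_m, ic_minus_2sd = lo_m, a = a_m,
                 period_edges = period_edges, cumulative = cumulative),
            class = "faers_temporal")
}

#' @export
print.faers_temporal <- function(x, ...) {
  cat(sprintf("<faers_temporal> %d terms x %d periods (%s)\n",
              nrow(x$ic), ncol(x$ic),
              if (x$cumulative) "cumulative" else "per-period"))
  invisible(x)
}

#' Time-to-onset summary
#'
#' Onset is the number of days from therapy start to the adverse event.
#' Records lacking either date contribute nothing; negative onsets are
#' excluded and counted. Quantiles use linear interpolation (type 7). The
#' binning is inclusive at both printed endpoints (`31-60` means
#' `31 <= d <= 60`; day 0 falls in the first bin).
#'
#' @param x A `faers_analysis_set` (onset computed for focal cases from
#'   `event_dt` and `therapy_start`) or a numeric vector of onset days.
#' @param ... Unused.
#' @return An `onset_summary`: `n`, `median_days`, `q1_days`, `q3_days`,
#'   `bin_counts` over `0-30, 31-60, 61-90, 91-120, 121-150, 151-180,
#'   181-360, >360` days, `n_negative`, `n_missing`.
#' @export
compute_onset <- function(x, ...) UseMethod("compute_onset")

onset_bin_edges <- data.frame(
  label = c("0-30", "31-60", "61-90", "91-120", "121-150", "151-180",
            "181-360", ">360"),
  lo = c(0, 31, 61, 91, 121, 151, 181, 361),
  hi = c(30, 60, 90, 120, 150, 180, 360, Inf),
  stringsAsFactors = FALSE
)

#' @rdname compute_onset
#' @export
compute_onset.numeric <- function(x, ...) {
  n_missing <- sum(is.na(x))
  d <- x[!is.na(x)]
  n_negative <- sum(d < 0)
  d <- d[d >= 0]
  bins <- vapply(seq_len(nrow(onset_bin_edges)), function(i) {
    sum(d >= onset_bin_edges$lo[i] & d <= onset_bin_edges$hi[i])
  }, integer(1))
  names(bins) <- onset_bin_edges$label
  q <- if (length(d)) stats::quantile(d, c(0.25, 0.5, 0.75), type = 7,
                                      names = FALSE) else rep(NA_real_, 3)
  structure(list(n = length(d), median_days = q[2], q1_days = q[1],
                 q3_days = q[3], bin_counts = bins,
                 n_negative = n_negative, n_missing = n_missing),
            class = "onset_summary")
}

#' @rdname compute_onset
#' @export
compute_onset.faers_analysis_set <- function(x, ...) {
  r <- x$records[x$records$focal, , drop = FALSE]
  ev <- ymd_to_date(r$event_dt)
  ts <- ymd_to_date(r$therapy_start)
  days <- as.numeric(ev - ts)
  compute_onset(days)
}

#' @export
print.onset_summary <- function(x, ...) {
  cat("<onset_summary>\n")
  cat(sprintf("  n = %d (negative excluded: %d, missing: %d)\n",
              x$n, x$n_negative, x$n_missing))
  cat(sprintf("  median %.1f days (IQR %.1f-%.1f)\n",
              x$median_days, x$q1_days, x$q3_days))
  print(x$bin_counts)
  invisible(x)
}

#' Demographic and clinical summary of the focal caseload
#'
#' Tabulates counts and percentages (denominator: all focal cases, including
#' unknowns) for sex, age group, reporting year, reporter occupation, top-5
#' reporting countries, seriousness and outcome codes, plus a weight summary
#' (mean/SD, median and quartiles, range, missing count).
#'
#' @param x A `faers_analysis_set` (focal records used) or a records
#'   `data.frame`.
#' @param ... Unused.
#' @return A `faers_demographics` object: `$categories` is a `data.frame`
#'   (`category`, `level`, `n`, `pct`), `$weight` a named list, `$n_total`
#'   the case count.
#' @export
summarize_demographics <- function(x, ...) UseMethod("summarize_demographics")

#' @rdname summarize_demographics
#' @export
summarize_demographics.faers_analysis_set <- function(x, ...) {
  summarize_demographics(x$records[x$records$focal, , drop = FALSE])
}

#' @rdname summarize_demographics
#' @export
summarize_demographics.data.frame <- function(x, ...) {
  n <- nrow(x)
  one <- function(category, values, top = NULL, levels = NULL) {
    values <- as.character(values)
    values[is.na(values)] <- "unknown"
    tab <- sort(table(values), decreasing = TRUE)
    if (!is.null(top)) tab <- tab[seq_len(min(top, length(tab)))]
    if (!is.null(levels)) {
      tab <- table(factor(values, levels = levels))
    }
    data.frame(category = category, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / n, 2),
               stringsAsFactors = FALSE)
  }
  outc <- strsplit(ifelse(is.na(x$outcomes), "", x$outcomes), ";", fixed = TRUE)
  outc_codes <- c(LT = "life-threatening", HO = "hospitalization",
                  DS = "disability", DE = "death", CA = "congenital anomaly",
                  RI = "required intervention", OT = "other")
  outc_n <- vapply(names(outc_codes),
                   function(k) sum(vapply(outc, function(v) k %in% v, TRUE)),
                   integer(1))
  cats <- rbind(
    one("sex", x$sex, levels = c("female", "male", "unknown")),
    one("age_group", x$age_group,
        levels = c("<18", "18-44", "45-64", "65-74", ">=75", "unknown")),
    one("report_year", x$report_year),
    one("reporter", x$reporter),
    one("country", x$country, top = 5),
    one("serious", x$serious, levels = c("serious", "non-serious")),
    data.frame(category = "outcome", level = unname(outc_codes),
               n = unname(outc_n), pct = round(100 * unname(outc_n) / n, 2),
               stringsAsFactors = FALSE)
  )
  w <- x$weight_kg
  weight <- list(
    n = sum(!is.na(w)), missing = sum(is.na(w)),
    mean = mean(w, na.rm = TRUE), sd = stats::sd(w, na.rm = TRUE),
    median = stats::median(w, na.rm = TRUE),
    q1 = unname(stats::quantile(w, 0.25, na.rm = TRUE, type = 7)),
    q3 = unname(stats::quantile(w, 0.75, na.rm = TRUE, type = 7)),
    min = suppressWarnings(min(w, na.rm = TRUE)),
    max = suppressWarnings(max(w, na.rm = TRUE))
  )
  structure(list(categories = cats, weight = weight, n_total = n),
            class = "faers_demographics")
}

#' @export
print.faers_demographics <- function(x, ...) {
  cat(sprintf("<faers_demographics> %d cases\n", x$n_total))
  print(x$categories, row.names = FALSE)
  if (x$weight$n > 0) {
    cat(sprintf("weight (kg): n=%d missing=%d mean=%.2f sd=%.2f median=%.2f (%.2f, %.2f)\n",
                x$weight$n, x$weight$missing, x$weight$mean, x$weight$sd,
                x$weight$median, x$weight$q1, x$weight$q3))
  }
  invisible(x)
}
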