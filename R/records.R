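#' Build an analysis-ready dataset from raw FAERS tables
#'
#' Deduplicates the cases, identifies the cases reporting the focal drug as
#' (by default) primary suspect, and joins demographics, therapy start dates
#' and reactions into the flat structures the downstream analyses use.
#'
#' @param data A `faers_data` object.
#' @param dictionary Focal-drug name patterns (see [filter_focal_drug()]).
#' @param roles FAERS drug role codes defining exposure; default `"PS"`.
#' @param pt_soc_map Optional PT-to-SOC map (see [read_pt_soc_map()]).
#' @return A `faers_analysis_set`: list with
#'   \describe{
#'     \item{records}{one row per deduplicated case: `case_id`, `sex`,
#'       `age_years`, `age_group`, `weight_kg`, `country`, `reporter`,
#'       `report_year`, `serious`, `outcomes`, `event_dt`, `therapy_start`,
#'       `focal`}
#'     \item{reactions}{one row per reported event: `case_id`, `pt`, plus the
#'       case's `report_year`, `sex`, `age_group`, `serious` for
#'       stratification}
#'     \item{focal_ids}{case ids exposed to the focal drug}
#'     \item{pt_soc_map}{the map, or `NULL`}
#'   }
#' @export
prepare_analysis <- function(data, dictionary, roles = "PS", pt_soc_map = NULL) {
  stopifnot(inherits(data, "faers_data"))
  data <- deduplicate(data)
  focal_ids <- filter_focal_drug(data$drug, dictionary, roles)

  demo <- data$demo
  sex <- rep("unknown", nrow(demo))
  if ("sex" %in% names(demo)) {
    sex[demo$sex %in% c("F", "f")] <- "female"
    sex[demo$sex %in% c("M", "m")] <- "male"
  }
  age_years <- if ("age" %in% names(demo)) {
    age_in_years(demo$age, if ("age_cod" %in% names(demo)) demo$age_cod else NA)
  } else rep(NA_real_, nrow(demo))
  yr_src <- if ("init_fda_dt" %in% names(demo) &&
                !all(is.na(demo$init_fda_dt))) demo$init_fda_dt else demo$fda_dt
  report_year <- suppressWarnings(as.integer(yr_src %/% 10000))

  occ <- if ("occp_cod" %in% names(demo)) demo$occp_cod else rep(NA, nrow(demo))
  reporter <- c(CN = "consumer", MD = "physician", PH = "pharmacist")[occ]
  reporter[is.na(reporter)] <- "not specified"

  serious <- rep(NA_character_, nrow(demo))
  if ("serious" %in% names(demo)) {
    serious <- ifelse(demo$serious %in% c("Y", "1", "yes"), "serious",
                      ifelse(is.na(demo$serious), NA, "non-serious"))
  }

  therapy_start <- rep(NA_real_, nrow(demo))
  if (!is.null(data$ther) && nrow(data$ther) > 0L) {
    ts <- stats::aggregate(start_dt ~ caseid, data = data$ther,
                           FUN = min, na.rm = TRUE)
    idx <- match(demo$caseid, ts$caseid)
    therapy_start <- ts$start_dt[idx]
  }

  records <- data.frame(
    case_id = as.character(demo$caseid),
    sex = sex,
    age_years = age_years,
    age_group = assign_age_group(age_years),
    weight_kg = if ("wt" %in% names(demo)) demo$wt else NA_real_,
    country = if ("reporter_country" %in% names(demo))
      demo$reporter_country else NA_character_,
    reporter = reporter,
    report_year = report_year,
    serious = serious,
    outcomes = if ("outc_cod" %in% names(demo)) demo$outc_cod else NA_character_,
    event_dt = if ("event_dt" %in% names(demo)) demo$event_dt else NA_real_,
    therapy_start = therapy_start,
    stringsAsFactors = FALSE
  )
  records$focal <- records$case_id %in% focal_ids

  reac <- data$reac
  idx <- match(as.character(reac$caseid), records$case_id)
  reactions <- data.frame(
    case_id = as.character(reac$caseid),
    pt = reac$pt,
    report_year = records$report_year[idx],
    sex = records$sex[idx],
    age_group = records$age_group[idx],
    serious = records$serious[idx],
    stringsAsFactors = FALSE
  )

  out <- list(records = records, reactions = reactions, focal_ids = focal_ids,
              pt_soc_map = pt_soc_map)
  class(out) <- "faers_analysis_set"
  out
}

#' @export
print.faers_analysis_set <- function(x, ...) {
  cat("<faers_analysis_set>\n")
  cat(sprintf("  cases: %d (focal: %d)\n", nrow(x$records),
              length(x$focal_ids)))
  cat(sprintf("  events: %d (focal: %d)\n", nrow(x$reactions),
              sum(x$reactions$case_id %in% x$focal_ids)))
  invisible(x)
}

# Restrict an analysis set to a stratum (sex / age_group / report period).
subset_analysis_set <- function(set, sex = NULL, age_group = NULL,
                                period = NULL, serious = NULL) {
  keep <- rep(TRUE, nrow(set$records))
  r <- set$records
  if (!is.null(sex)) keep <- keep & r$sex %in% sex
  if (!is.null(age_group)) keep <- keep & r$age_group %in% age_group
  if (!is.null(serious)) keep <- keep & r$serious %in% serious
  if (!is.null(period)) {
    keep <- keep & !is.na(r$report_year) &
      r$report_year >= period[1] & r$report_year <= period[2]
  }
  ids <- r$case_id[keep]
  set$records <- r[keep, , drop = FALSE]
  set$reactions <- set$reactions[set$reactions$case_id %in% ids, , drop = FALSE]
  set$focal_ids <- intersect(set$focal_ids, ids)
  set
}
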