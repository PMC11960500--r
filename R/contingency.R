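#' Build drug-event 2x2 contingency tables
#'
#' Cross-tabulates reported events against focal-drug exposure at Preferred
#' Term or System Organ Class level. For each term the cells are: `a` focal
#' records with the term, `b` focal records with other terms, `c` background
#' records with the term, `d` the remainder.
#'
#' Two counting units are supported. With `unit = "event"` every reported
#' drug-event pair counts once, so `a + b` is the focal event total. With
#' `unit = "report"` a case contributes at most once to any term, so `a + b`
#' is the number of focal cases. Event counting is the convention for PT-level
#' tables; report counting for SOC-level tables, where one case typically
#' reports several terms of the same class.
#'
#' @param reactions A reactions `data.frame` with `case_id` and `pt` (e.g. the
#'   `reactions` element of a [prepare_analysis()] result).
#' @param focal_ids Case ids exposed to the focal drug.
#' @param level `"PT"` or `"SOC"`.
#' @param pt_soc_map Required when `level = "SOC"`; PTs absent from the map are
#'   tallied under the pseudo-class `"unmapped"` with a warning.
#' @param unit `"event"` or `"report"` (see Details).
#' @param grand_total Optional override of the database margin `N` (event
#'   unit only), e.g. the full-database REAC record count when the background
#'   corpus is a sample.
#' @return `data.frame` with columns `term`, `level`, `a`, `b`, `c`, `d`,
#'   sorted by decreasing `a`.
#' @export
build_contingency <- function(reactions, focal_ids,
                              level = c("PT", "SOC"), pt_soc_map = NULL,
                              unit = c("event", "report"),
                              grand_total = NULL) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  if (nrow(reactions) == 0L) {
    stop_faers("no reactions to tabulate", class = "faers_empty_error")
  }
  term <- reactions$pt
  if (level == "SOC") {
    if (is.null(pt_soc_map)) {
      stop_faers("SOC level requires a pt_soc_map", class = "faers_config_error")
    }
    soc <- pt_soc_map$soc[match(term, pt_soc_map$pt)]
    if (anyNA(soc)) {
      warning(sprintf("%d event(s) with PT absent from the map counted as 'unmapped'",
                      sum(is.na(soc))), call. = FALSE)
      soc[is.na(soc)] <- "unmapped"
    }
    term <- soc
  }
  focal <- reactions$case_id %in% focal_ids

  if (unit == "report") {
    key <- !duplicated(paste(reactions$case_id, term, sep = "\r"))
    term_u <- term[key]
    focal_u <- focal[key]
    n_focal <- length(unique(reactions$case_id[focal]))
    n_bg <- length(unique(reactions$case_id[!focal]))
    a <- table(factor(term_u[focal_u], levels = sort(unique(term))))
    c_ <- table(factor(term_u[!focal_u], levels = sort(unique(term))))
    out <- data.frame(term = names(a), level = level,
                      a = as.integer(a), c = as.integer(c_),
                      stringsAsFactors = FALSE)
    out$b <- n_focal - out$a
    out$d <- n_bg - out$c
  } else {
    a <- table(factor(term[focal], levels = sort(unique(term))))
    c_ <- table(factor(term[!focal], levels = sort(unique(term))))
    drug_total <- sum(focal)
    N <- grand_total %||% length(term)
    if (N < length(term)) {
      stop_faers("grand_total smaller than the observed event count",
                 class = "faers_value_error")
    }
    out <- data.frame(term = names(a), level = level,
                      a = as.integer(a), c = as.integer(c_),
                      stringsAsFactors = FALSE)
    out$b <- drug_total - out$a
    out$d <- (N - drug_total) - out$c
  }
  out <- out[order(-out$a, out$term), c("term", "level", "a", "b", "c", "d")]
  rownames(out) <- NULL
  out
}

#' Reconstruct a 2x2 table from published statistics
#'
#' Given a published case count `a` and reporting odds ratio together with the
#' focal-drug event margin and the database event total, recovers the
#' background cells by inverting the ROR identity:
#' `b = drug_total - a`, `S = grand_total - drug_total`,
#' `c = round(a * S / (ror * b + a))`, `d = S - c`. The recomputed ROR of the
#' returned table is checked to lie within 1% of the input.
#'
#' @param a Published case count(s), `>= 1`.
#' @param ror Published reporting odds ratio(s), `> 0`.
#' @param drug_total Focal-drug event margin (`a + b`).
#' @param grand_total Database event total `N`.
#' @param flag_infeasible If `TRUE`, rows whose reconstruction fails
#'   (`c` rounds to 0) are returned with `feasible = FALSE` instead of
#'   raising an error.
#' @return `data.frame` with columns `a`, `b`, `c`, `d`, `feasible`.
#' @examples
#' reconstruct_contingency(141, 53538.3, 1095, 54336884)
#' @export
reconstruct_contingency <- function(a, ror, drug_total, grand_total,
                                    flag_infeasible = FALSE) {
  if (any(a < 1) || any(ror <= 0) || any(drug_total < a) ||
      any(grand_total <= drug_total)) {
    stop_faers("need a >= 1, ror > 0, drug_total >= a, grand_total > drug_total",
               class = "faers_value_error")
  }
  b <- drug_total - a
  S <- grand_total - drug_total
  c_ <- round(a * S / (ror * b + a))
  d <- S - c_
  feasible <- c_ >= 1
  if (!flag_infeasible && any(!feasible)) {
    stop_faers("reconstruction infeasible: background cell rounds to 0",
               class = "faers_infeasible_error")
  }
  out <- data.frame(a = a, b = b, c = c_, d = d, feasible = feasible)
  chk <- feasible & b > 0
  rel <- abs((out$a * out$d) / (out$b * out$c) - ror) / ror
  if (any(chk & rel > 0.01)) {
    warning("reconstructed ROR deviates more than 1% from the input for ",
            sum(chk & rel > 0.01), " row(s)", call. = FALSE)
  }
  out
}

#' Share of each term among focal-drug events
#'
#' @param reactions Reactions `data.frame` (`case_id`, `pt`).
#' @param focal_ids Focal case ids.
#' @param level,pt_soc_map As in [build_contingency()].
#' @return `data.frame` with `term`, `n`, `pct` (percent of focal events,
#'   2 decimals), sorted by decreasing `n`.
#' @export
term_distribution <- function(reactions, focal_ids, level = c("PT", "SOC"),
                              pt_soc_map = NULL) {
  level <- match.arg(level)
  foc <- reactions[reactions$case_id %in% focal_ids, , drop = FALSE]
  term <- foc$pt
  if (level == "SOC") {
    if (is.null(pt_soc_map)) {
      stop_faers("SOC level requires a pt_soc_map", class = "faers_config_error")
    }
    term <- pt_soc_map$soc[match(term, pt_soc_map$pt)]
    term[is.na(term)] <- "unmapped"
  }
  tab <- sort(table(term), decreasing = TRUE)
  data.frame(term = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / nrow(foc), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
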