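# Synthetic FAERS generator: emits DEMO/DRUG/REAC/THER tables in the same
# "$"-delimited dialect the ingest module reads, with controlled background
# event rates, implanted drug-event association strengths, calibrated
# demographics, an onset-time distribution and duplicate case versions.

#' Configure the synthetic FAERS generator
#'
#' @param n_background_reports,n_focal_reports Report counts for the
#'   background corpus and the focal drug.
#' @param pt_vocabulary `data.frame` with `pt`, `soc`,
#'   `background_probability` (must sum to 1).
#' @param implanted_rr Named numeric: relative-risk multiplier applied to the
#'   named PTs' probabilities for focal reports (renormalised). Under this
#'   multiplicative model the event-level odds ratio of an implanted PT equals
#'   its multiplier exactly. Names must be a subset of the vocabulary.
#' @param events_per_report `list(mean =, max =)`: events per report are
#'   `1 + Geometric`, truncated at `max`.
#' @param demographics List of named probability vectors `sex`, `age_group`,
#'   `year`, `reporter`, `country`, `serious` (each summing to 1) and
#'   `outcome` (independent per-code probabilities, need not sum to 1).
#' @param weight `list(mean, sd, min, max, p_missing)`: truncated-normal
#'   body weight in kg.
#' @param onset `list(family, shape, scale, p_observed)`: time-to-onset
#'   distribution (`"weibull"` or `"lognormal"`, where `shape`/`scale` are
#'   `meanlog`/`sdlog`) and the fraction of focal reports carrying both dates.
#' @param duplicate_rate Fraction of cases emitted twice with an extra,
#'   earlier report version.
#' @param seed Integer; fully determines the generator output.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_background_reports = 1e5,
                             n_focal_reports = 510,
                             pt_vocabulary = default_vocabulary(),
                             implanted_rr = numeric(0),
                             events_per_report = list(mean = 2.1, max = 10),
                             demographics = default_demographics(),
                             weight = list(mean = 71.5, sd = 16.4,
                                           min = 34.2, max = 132,
                                           p_missing = 2 / 3),
                             onset = list(family = "weibull", shape = 1.5,
                                          scale = 180, p_observed = 0.43),
                             duplicate_rate = 0.1,
                             seed = 1L) {
  stopifnot(is.data.frame(pt_vocabulary),
            all(c("pt", "soc", "background_probability") %in%
                  names(pt_vocabulary)))
  p <- pt_vocabulary$background_probability
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop_faers("vocabulary background probabilities must be >= 0 and sum to 1",
               class = "faers_config_error")
  }
  if (length(implanted_rr)) {
    if (is.null(names(implanted_rr)) ||
        !all(names(implanted_rr) %in% pt_vocabulary$pt)) {
      stop_faers("implanted_rr names must be vocabulary PTs",
                 class = "faers_config_error")
    }
    if (any(implanted_rr <= 0)) {
      stop_faers("implanted_rr multipliers must be positive",
                 class = "faers_config_error")
    }
  }
  for (nm in c("sex", "age_group", "year", "reporter", "country", "serious")) {
    v <- demographics[[nm]]
    if (is.null(v) || any(v < 0) || abs(sum(v) - 1) > 1e-6) {
      stop_faers("demographics$", nm, " must be probabilities summing to 1",
                 class = "faers_config_error")
    }
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop_faers("duplicate_rate must be in [0, 1)", class = "faers_config_error")
  }
  if (!onset$family %in% c("weibull", "lognormal")) {
    stop_faers("onset$family must be weibull or lognormal",
               class = "faers_config_error")
  }
  structure(list(n_background_reports = as.integer(n_background_reports),
                 n_focal_reports = as.integer(n_focal_reports),
                 pt_vocabulary = pt_vocabulary, implanted_rr = implanted_rr,
                 events_per_report = events_per_report,
                 demographics = demographics, weight = weight, onset = onset,
                 duplicate_rate = duplicate_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  reports: %d background + %d focal; %d PTs; %d implanted RR\n",
              x$n_background_reports, x$n_focal_reports,
              nrow(x$pt_vocabulary), length(x$implanted_rr)))
  cat(sprintf("  onset: %s(%.3g, %.3g), duplicates: %.0f%%, seed: %d\n",
              x$onset$family, x$onset$shape, x$onset$scale,
              100 * x$duplicate_rate, x$seed))
  invisible(x)
}

#' Default synthetic PT vocabulary with background rates
#'
#' Takes the bundled synthetic PT-to-SOC vocabulary and attaches background
#' reporting probabilities: the known aducanumab signal PTs receive the rare
#' background rates implied by their published share and strength
#' (`share / EBGM`, since the EBGM approximates the relative reporting rate),
#' and the filler PTs split the remaining mass in proportions typical of
#' common spontaneous-report terms.
#'
#' @return `data.frame` with `pt`, `soc`, `background_probability`.
#' @export
default_vocabulary <- function() {
  map <- synthetic_pt_soc_map()
  pub <- published_reference("pt")
  share <- pub$n / sum(pub$n)
  p_sig <- share / pub$ebgm
  p <- numeric(nrow(map))
  names(p) <- map$pt
  p[pub$term] <- p_sig
  filler <- setdiff(map$pt, pub$term)
  # heavier mass on the classic high-volume terms
  wts <- ifelse(filler %in% c("Nausea", "Fatigue", "Drug ineffective",
                              "Off label use", "Headache", "Dizziness"),
                3, 1)
  p[filler] <- (1 - sum(p_sig)) * wts / sum(wts)
  map$background_probability <- unname(p)
  map
}

default_demographics <- function() {
  list(
    sex = c(female = 0.48, male = 0.47, unknown = 0.05),
    age_group = c(`<18` = 0.02, `18-44` = 0.18, `45-64` = 0.3,
                  `65-74` = 0.2, `>=75` = 0.15, unknown = 0.15),
    year = c(`2021` = 0.2, `2022` = 0.3, `2023` = 0.3, `2024` = 0.2),
    reporter = c(consumer = 0.4, physician = 0.3, pharmacist = 0.2,
                 `not specified` = 0.1),
    country = c(`United States` = 0.8, Japan = 0.05, Canada = 0.05,
                France = 0.04, Switzerland = 0.03, Other = 0.03),
    serious = c(serious = 0.5, `non-serious` = 0.5),
    outcome = c(`life-threatening` = 0.02, hospitalization = 0.2,
                disability = 0.005, death = 0.05, `congenital anomaly` = 0,
                `required intervention` = 0.005, other = 0.25)
  )
}

#' Fit a parametric onset distribution to binned counts
#'
#' Maximum likelihood over binned data: the log-likelihood is
#' `sum(n_k log(F(u_k) - F(l_k)))` with the last bin open-ended. Integer day
#' bins `[lo, hi]` are treated as the continuous interval `[lo, hi + 1)`.
#'
#' @param counts Counts per bin.
#' @param lower,upper Inclusive integer bin edges (`upper` may end in `Inf`).
#' @param family `"weibull"`, `"lognormal"` or `"exponential"`.
#' @return List with `family`, `par` (named), `loglik` and the fitted
#'   `median` in days.
#' @export
fit_onset_dist <- function(counts,
                           lower = onset_bin_edges$lo,
                           upper = onset_bin_edges$hi,
                           family = c("weibull", "lognormal", "exponential")) {
  family <- match.arg(family)
  stopifnot(length(counts) == length(lower), length(lower) == length(upper))
  up <- ifelse(is.finite(upper), upper + 1, Inf)
  cdf <- switch(family,
    weibull = function(x, th) stats::pweibull(x, exp(th[1]), exp(th[2])),
    lognormal = function(x, th) stats::plnorm(x, th[1], exp(th[2])),
    exponential = function(x, th) stats::pexp(x, exp(th[1]))
  )
  nll <- function(th) {
    pr <- cdf(up, th) - cdf(lower, th)
    if (any(pr <= 0)) return(1e12)
    -sum(counts * log(pr))
  }
  th0 <- switch(family, weibull = c(log(1.5), log(150)),
                lognormal = c(log(120), log(1)), exponential = log(1 / 150))
  fit <- if (family == "exponential") {
    stats::optim(th0, nll, method = "Brent", lower = -15, upper = 0)
  } else {
    stats::optim(th0, nll, method = "Nelder-Mead")
  }
  th <- fit$par
  par <- switch(family,
    weibull = c(shape = exp(th[1]), scale = exp(th[2])),
    lognormal = c(meanlog = th[1], sdlog = exp(th[2])),
    exponential = c(rate = exp(th[1]))
  )
  med <- switch(family,
    weibull = stats::qweibull(0.5, par[1], par[2]),
    lognormal = stats::qlnorm(0.5, par[1], par[2]),
    exponential = stats::qexp(0.5, par[1])
  )
  list(family = family, par = par, loglik = -fit$value, median = unname(med))
}

#' Generator profile calibrated to the published aducanumab caseload
#'
#' Returns a frozen [synthetic_config()] whose demographic category
#' probabilities equal the published proportions (510 reports: sex, age
#' groups, reporting years, reporter occupations, countries, seriousness,
#' outcomes), whose weight distribution is normal(71.49, 16.36) truncated to
#' [34.2, 132.0] kg with the published missingness, whose onset distribution
#' is a Weibull fitted by binned maximum likelihood to the published
#' onset-bin counts (217 of 510 reports with computable onset), and whose
#' events-per-report mean matches 1,095 events over 510 reports. The
#' implanted relative-risk multipliers are the published EBGM values of the
#' 27 signal PTs.
#'
#' @param n_background_reports Background corpus size; the default is
#'   desk-scale rather than the tens of millions of a full database extract.
#' @param seed Root seed.
#' @return A `synthetic_config`.
#' @export
aducanumab_profile <- function(n_background_reports = 1e5, seed = 1L) {
  dem <- published_reference("demographics")
  pub <- published_reference("pt")
  get <- function(cat) {
    d <- dem[dem$category == cat, ]
    stats::setNames(d$value, d$level)
  }
  total <- unname(get("total"))
  prop <- function(cat) {
    v <- get(cat)
    v / sum(v)
  }
  onset_counts <- get("onset_bin")
  ofit <- fit_onset_dist(onset_counts, family = "weibull")
  wt <- get("weight")
  outc <- get("outcome") / total
  names(outc) <- names(get("outcome"))
  synthetic_config(
    n_background_reports = n_background_reports,
    n_focal_reports = total,
    pt_vocabulary = default_vocabulary(),
    implanted_rr = stats::setNames(pub$ebgm, pub$term),
    events_per_report = list(mean = unname(get("event_total")) / total,
                             max = 10),
    demographics = list(sex = prop("sex"), age_group = prop("age_group"),
                        year = prop("report_year"), reporter = prop("reporter"),
                        country = prop("country"), serious = prop("serious"),
                        outcome = outc),
    weight = list(mean = wt[["mean"]], sd = wt[["sd"]], min = wt[["min"]],
                  max = wt[["max"]], p_missing = wt[["missing"]] / total),
    onset = list(family = "weibull", shape = unname(ofit$par["shape"]),
                 scale = unname(ofit$par["scale"]),
                 p_observed = sum(onset_counts) / total),
    duplicate_rate = 0.1,
    seed = seed
  )
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

age_from_group <- function(groups) {
  lo <- c(`<18` = 1, `18-44` = 18, `45-64` = 45, `65-74` = 65, `>=75` = 75)
  hi <- c(`<18` = 17.9, `18-44` = 44.9, `45-64` = 64.9, `65-74` = 74.9,
          `>=75` = 94.9)
  out <- rep(NA_real_, length(groups))
  known <- groups %in% names(lo)
  out[known] <- round(stats::runif(sum(known), lo[groups[known]],
                                   hi[groups[known]]), 1)
  out
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic FAERS dataset
#'
#' Emits a `faers_data` object (DEMO/DRUG/REAC/THER) in the quarterly ASCII
#' dialect. Focal reports carry the focal drug as primary suspect, their PT
#' draws use the background probabilities multiplied by the implanted
#' relative risks (renormalised), onset days are drawn from the configured
#' distribution, and a configurable fraction of cases appears twice with a
#' distinct, earlier report version. Output is fully determined by the seed.
#'
#' @param config A [synthetic_config()].
#' @param focal_drug Name written for focal primary-suspect entries.
#' @return A `faers_data` object; write it to disk with [write_faers_data()].
#' @export
generate_faers <- function(config, focal_drug = "ADUCANUMAB") {
  stopifnot(inherits(config, "synthetic_config"))
  n_bg <- config$n_background_reports
  n_fc <- config$n_focal_reports
  n <- n_bg + n_fc
  focal <- c(rep(FALSE, n_bg), rep(TRUE, n_fc))
  caseid <- c(sprintf("1%07d", seq_len(n_bg)), sprintf("9%07d", seq_len(n_fc)))

  set.seed(substream_seed(config$seed, "demographics"))
  dg <- config$demographics
  sex_cat <- sample_cat(n, dg$sex)
  sex <- c(female = "F", male = "M", unknown = NA)[sex_cat]
  grp <- sample_cat(n, dg$age_group)
  age <- age_from_group(grp)
  year <- as.integer(sample_cat(n, dg$year))
  fda_dt <- year * 10000 + sample(1:12, n, TRUE) * 100 + sample(1:28, n, TRUE)
  occ <- c(consumer = "CN", physician = "MD", pharmacist = "PH",
           `not specified` = NA)[sample_cat(n, dg$reporter)]
  country <- sample_cat(n, dg$country)
  serious <- c(serious = "Y", `non-serious` = "N")[sample_cat(n, dg$serious)]
  wt <- round(rtruncnorm(n, config$weight$mean, config$weight$sd,
                         config$weight$min, config$weight$max), 1)
  wt[stats::runif(n) < config$weight$p_missing] <- NA
  oc <- config$demographics$outcome
  outc <- vapply(seq_len(n), function(i) {
    codes <- c(`life-threatening` = "LT", hospitalization = "HO",
               disability = "DS", death = "DE", `congenital anomaly` = "CA",
               `required intervention` = "RI", other = "OT")
    hit <- stats::runif(length(oc)) < oc
    paste(codes[names(oc)[hit]], collapse = ";")
  }, character(1))
  outc[outc == ""] <- NA

  set.seed(substream_seed(config$seed, "events"))
  m <- config$events_per_report$mean
  k <- pmin(1 + stats::rgeom(n, 1 / m), config$events_per_report$max)
  voc <- config$pt_vocabulary
  p_bg <- voc$background_probability
  p_fc <- p_bg
  if (length(config$implanted_rr)) {
    idx <- match(names(config$implanted_rr), voc$pt)
    p_fc[idx] <- p_fc[idx] * config$implanted_rr
  }
  p_fc <- p_fc / sum(p_fc)
  reac_case <- rep(caseid, k)
  reac_focal <- rep(focal, k)
  pts <- character(sum(k))
  pts[!reac_focal] <- sample(voc$pt, sum(k[!focal]), TRUE, prob = p_bg)
  pts[reac_focal] <- sample(voc$pt, sum(k[focal]), TRUE, prob = p_fc)

  set.seed(substream_seed(config$seed, "onset"))
  onset_days <- rep(NA_real_, n)
  obs <- focal & stats::runif(n) < config$onset$p_observed
  nd <- sum(obs)
  draw <- if (config$onset$family == "weibull") {
    stats::rweibull(nd, config$onset$shape, config$onset$scale)
  } else {
    stats::rlnorm(nd, config$onset$shape, config$onset$scale)
  }
  onset_days[obs] <- floor(draw)
  event_date <- ymd_to_date(fda_dt) - sample(0:60, n, TRUE)
  start_date <- event_date - onset_days
  event_dt <- ifelse(obs, date_to_ymd(event_date), NA_real_)
  start_dt <- ifelse(obs, date_to_ymd(start_date), NA_real_)

  primaryid <- paste0(caseid, "2")
  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = 2,
    fda_dt = fda_dt, event_dt = event_dt, age = age,
    age_cod = ifelse(is.na(age), NA, "YR"), sex = sex,
    wt = wt, wt_cod = ifelse(is.na(wt), NA, "KG"),
    reporter_country = country, occp_cod = occ,
    serious = serious, outc_cod = outc, stringsAsFactors = FALSE
  )
  bg_drugs <- c("ASPIRIN", "METFORMIN", "LISINOPRIL", "ATORVASTATIN",
                "OMEPRAZOLE", "AMLODIPINE", "LEVOTHYROXINE")
  drug <- data.frame(
    primaryid = primaryid, caseid = caseid, drug_seq = 1, role_cod = "PS",
    drugname = ifelse(focal, focal_drug, sample(bg_drugs, n, TRUE)),
    stringsAsFactors = FALSE
  )
  reac <- data.frame(
    primaryid = rep(primaryid, k), caseid = reac_case, pt = pts,
    stringsAsFactors = FALSE
  )
  ther <- data.frame(
    primaryid = primaryid[obs], caseid = caseid[obs], dsg_drug_seq = 1,
    start_dt = start_dt[obs], stringsAsFactors = FALSE
  )

  set.seed(substream_seed(config$seed, "duplicates"))
  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    dpid <- paste0(caseid[di], "1")
    d_demo <- demo[di, , drop = FALSE]
    d_demo$primaryid <- dpid
    d_demo$caseversion <- 1
    d_demo$fda_dt <- d_demo$fda_dt - 100  # an earlier receipt date
    demo <- rbind(demo, d_demo)
    d_drug <- drug[di, , drop = FALSE]
    d_drug$primaryid <- dpid
    drug <- rbind(drug, d_drug)
    d_reac <- reac[reac$primaryid %in% primaryid[di], , drop = FALSE]
    d_reac$primaryid <- paste0(d_reac$caseid, "1")
    reac <- rbind(reac, d_reac)
  }
  out <- list(demo = demo, drug = drug, reac = reac, ther = ther)
  class(out) <- "faers_data"
  attr(out, "config_seed") <- config$seed
  out
}
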