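# Shared fixture builders. Everything is generated in code; no binary files.

write_fixture <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# Random 2x2 tables with all cells positive.
random_tables <- function(n, seed, lambda = c(5, 50, 80, 5000)) {
  set.seed(seed)
  data.frame(
    a = rpois(n, lambda[1]) + 1, b = rpois(n, lambda[2]) + 1,
    c = rpois(n, lambda[3]) + 1, d = rpois(n, lambda[4]) + 1
  )
}

# Expand the published demographic counts into one record per case, so the
# summary can be checked against the printed percentages by pure arithmetic.
expand_demographic_records <- function() {
  dem <- published_reference("demographics")
  g <- function(cat) {
    d <- dem[dem$category == cat, ]
    stats::setNames(d$value, d$level)
  }
  n <- unname(g("total"))
  expand <- function(cat) rep(names(g(cat)), times = g(cat))
  # outcomes are non-exclusive; assign each code's count to the first rows
  outc <- rep(NA_character_, n)
  codes <- c(`life-threatening` = "LT", hospitalization = "HO",
             disability = "DS", death = "DE", `congenital anomaly` = "CA",
             `required intervention` = "RI", other = "OT")
  pos <- 1
  for (lv in names(g("outcome"))) {
    k <- g("outcome")[[lv]]
    if (k > 0) {
      idx <- seq(pos, length.out = k)
      idx <- ((idx - 1) %% n) + 1
      outc[idx] <- ifelse(is.na(outc[idx]), codes[[lv]],
                          paste(outc[idx], codes[[lv]], sep = ";"))
      pos <- pos + k
    }
  }
  data.frame(
    case_id = sprintf("C%03d", seq_len(n)),
    sex = expand("sex"),
    age_years = NA_real_,
    age_group = expand("age_group"),
    weight_kg = NA_real_,
    country = expand("country"),
    reporter = expand("reporter"),
    report_year = as.integer(expand("report_year")),
    serious = expand("serious"),
    outcomes = outc,
    stringsAsFactors = FALSE
  )
}

# Reactions table carrying the published focal event counts: the 27 signal
# PTs at their printed counts plus filler PTs up to the printed event total.
expand_published_reactions <- function() {
  pub <- published_reference("pt")
  total <- 1095L
  filler <- total - sum(pub$n)
  pts <- c(rep(pub$term, times = pub$n), rep("Fatigue", filler))
  data.frame(case_id = sprintf("F%04d", seq_along(pts)), pt = pts,
             stringsAsFactors = FALSE)
}

small_profile <- function(n_background = 5000, seed = 1) {
  aducanumab_profile(n_background_reports = n_background, seed = seed)
}
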