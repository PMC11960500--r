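# Known FAERS quarterly ASCII columns per table kind. `required` must all be
# present (after alias normalisation) for the header to be accepted; any other
# known column is carried through; truly unknown columns are reported in the
# schema error only when a required column is missing.
faers_schemas <- list(
  demo = list(
    required = c("primaryid", "caseid"),
    known = c("primaryid", "caseid", "caseversion", "i_f_code", "event_dt",
              "mfr_dt", "init_fda_dt", "fda_dt", "rept_cod", "auth_num",
              "mfr_num", "mfr_sndr", "lit_ref", "age", "age_cod", "age_grp",
              "sex", "e_sub", "wt", "wt_cod", "rept_dt", "to_mfr", "occp_cod",
              "reporter_country", "occr_country", "serious", "outc_cod"),
    aliases = c(gndr_cod = "sex", isr = "primaryid", case = "caseid",
                country = "reporter_country"),
    numeric = c("age", "wt", "fda_dt", "init_fda_dt", "event_dt", "rept_dt",
                "caseversion")
  ),
  drug = list(
    required = c("primaryid", "caseid", "role_cod", "drugname"),
    known = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
              "prod_ai", "val_vbm", "route", "dose_vbm", "cum_dose_chr",
              "cum_dose_unit", "dechal", "rechal", "lot_num", "exp_dt",
              "nda_num", "dose_amt", "dose_unit", "dose_form", "dose_freq"),
    aliases = c(isr = "primaryid", drug_name = "drugname"),
    numeric = c("drug_seq")
  ),
  reac = list(
    required = c("primaryid", "caseid", "pt"),
    known = c("primaryid", "caseid", "pt", "drug_rec_act", "event_dt"),
    aliases = c(isr = "primaryid", preferred_term = "pt"),
    numeric = c("event_dt")
  ),
  ther = list(
    required = c("primaryid", "caseid", "start_dt"),
    known = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt",
              "dur", "dur_cod"),
    aliases = c(isr = "primaryid"),
    numeric = c("dsg_drug_seq", "start_dt", "end_dt", "dur")
  )
)

#' Read one FAERS quarterly ASCII table
#'
#' Parses a `$`-delimited FAERS flat file (DEMO, DRUG, REAC or THER) with a
#' header row, normalising column names across quarterly vintages (e.g.
#' `gndr_cod` is mapped to `sex`, legacy `isr` to `primaryid`). Gzipped files
#' are read transparently. Rows with the wrong number of fields are padded or
#' truncated and counted; fields that fail numeric parsing become `NA` and are
#' counted. Neither is silently dropped: the total is attached as attribute
#' `malformed` and raised as a warning.
#'
#' @param path Path to the file (plain or gzip).
#' @param table_kind One of `"demo"`, `"drug"`, `"reac"`, `"ther"`.
#' @return A `data.frame` with normalised lower-case column names, attributes
#'   `table_kind` and `malformed` (count of repaired rows/fields).
#' @examples
#' f <- tempfile()
#' writeLines(c("primaryid$caseid$pt", "1001$100$Headache"), f)
#' read_faers_table(f, "reac")
#' @export
read_faers_table <- function(path, table_kind = c("demo", "drug", "reac", "ther")) {
  table_kind <- match.arg(table_kind)
  schema <- faers_schemas[[table_kind]]
  if (!file.exists(path)) {
    stop_faers("file not found: ", path, class = "faers_io_error")
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop_faers("empty input: ", path, class = "faers_empty_error")
  }
  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  hit <- schema$aliases[header]
  header[!is.na(hit)] <- hit[!is.na(hit)]
  missing_req <- setdiff(schema$required, header)
  if (length(missing_req) > 0L) {
    unknown <- setdiff(header, schema$known)
    stop_faers(
      "header does not match the ", toupper(table_kind), " schema; missing: ",
      paste(missing_req, collapse = ", "),
      if (length(unknown)) paste0("; unmatched columns: ",
                                  paste(unknown, collapse = ", ")),
      class = "faers_schema_error")
  }
  body <- lines[-1L][nzchar(lines[-1L])]
  ncol <- length(header)
  fields <- strsplit(body, "$", fixed = TRUE)
  lens <- lengths(fields)
  # A trailing empty field is dropped by strsplit; that is not malformation.
  short_ok <- lens == ncol - 1L
  fields[short_ok] <- lapply(fields[short_ok], function(f) c(f, ""))
  lens[short_ok] <- ncol
  malformed <- sum(lens != ncol)
  fields <- lapply(fields, function(f) {
    length(f) <- ncol
    f
  })
  mat <- do.call(rbind, fields)
  if (is.null(mat)) mat <- matrix(character(0), ncol = ncol)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df[df == ""] <- NA_character_
  for (nm in intersect(schema$numeric, header)) {
    raw <- df[[nm]]
    num <- suppressWarnings(as.numeric(raw))
    malformed <- malformed + sum(!is.na(raw) & is.na(num))
    df[[nm]] <- num
  }
  if (malformed > 0L) {
    warning(sprintf("%s: %d malformed row(s)/field(s) repaired (kept with NA)",
                    basename(path), malformed), call. = FALSE)
  }
  attr(df, "table_kind") <- table_kind
  attr(df, "malformed") <- malformed
  df
}

#' Write one table in the FAERS quarterly ASCII dialect
#'
#' Inverse of [read_faers_table()]: `$`-delimited with a header row, `NA`
#' written as the empty field.
#'
#' @param x A data.frame.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path) {
  fmt <- function(v) {
    out <- if (is.numeric(v)) {
      ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
    } else {
      ifelse(is.na(v), "", as.character(v))
    }
    out
  }
  cols <- lapply(x, fmt)
  lines <- c(paste(names(x), collapse = "$"),
             do.call(paste, c(cols, sep = "$")))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a set of FAERS tables into one object
#'
#' @param demo,drug,reac,ther Paths to the four quarterly tables (THER is
#'   optional: pass `NULL` when therapy dates are unavailable).
#' @return A `faers_data` object: a list with elements `demo`, `drug`, `reac`,
#'   `ther` (possibly `NULL`).
#' @export
read_faers_data <- function(demo, drug, reac, ther = NULL) {
  out <- list(
    demo = read_faers_table(demo, "demo"),
    drug = read_faers_table(drug, "drug"),
    reac = read_faers_table(reac, "reac"),
    ther = if (!is.null(ther)) read_faers_table(ther, "ther")
  )
  class(out) <- "faers_data"
  out
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data>\n")
  for (nm in c("demo", "drug", "reac", "ther")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: %d records, %d cases\n", toupper(nm), nrow(x[[nm]]),
                  length(unique(x[[nm]]$caseid))))
    }
  }
  invisible(x)
}

#' Write a `faers_data` object as FAERS-dialect flat files
#'
#' @param x A `faers_data` object.
#' @param dir Output directory (created if absent).
#' @param gzip Compress the files.
#' @return Named character vector of paths, invisibly.
#' @export
write_faers_data <- function(x, dir, gzip = FALSE) {
  stopifnot(inherits(x, "faers_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".txt.gz" else ".txt"
  paths <- character(0)
  for (nm in c("demo", "drug", "reac", "ther")) {
    if (is.null(x[[nm]])) next
    p <- file.path(dir, paste0(toupper(nm), ext))
    write_faers_table(x[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Deduplicate FAERS cases, keeping the latest report version
#'
#' FAERS carries multiple versions of the same case; standard practice retains
#' the most recent one. The version key is `(fda_dt, primaryid)` compared
#' lexicographically; the maximal key wins. Output is ordered by case id.
#'
#' @param x A `faers_data` object or a DEMO-like `data.frame` with a `caseid`
#'   column plus either a `version_key` column or `fda_dt`/`primaryid`.
#' @param ... Unused.
#' @return Same class as `x`, with one row per case in the DEMO table; for
#'   `faers_data` the DRUG/REAC/THER tables are restricted to the retained
#'   `primaryid`s.
#' @export
deduplicate <- function(x, ...) UseMethod("deduplicate")

dedup_keep <- function(caseid, key1, key2) {
  # index of the retained row per caseid: maximal (key1, key2)
  key1[is.na(key1)] <- -Inf
  key2[is.na(key2)] <- -Inf
  ord <- order(caseid, key1, key2)
  last <- !duplicated(caseid[ord], fromLast = TRUE)
  sort(ord[last])
}

#' @rdname deduplicate
#' @export
deduplicate.data.frame <- function(x, ...) {
  if (nrow(x) == 0L) return(x)
  if (!"caseid" %in% names(x)) {
    stop_faers("deduplicate needs a caseid column", class = "faers_value_error")
  }
  if ("version_key" %in% names(x)) {
    k1 <- as.numeric(x$version_key)
    k2 <- rep(0, nrow(x))
  } else {
    k1 <- suppressWarnings(as.numeric(x$fda_dt))
    k2 <- suppressWarnings(as.numeric(x$primaryid))
  }
  keep <- dedup_keep(x$caseid, k1, k2)
  out <- x[keep, , drop = FALSE]
  out <- out[order(out$caseid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname deduplicate
#' @export
deduplicate.faers_data <- function(x, ...) {
  x$demo <- deduplicate(x$demo)
  keep_pid <- x$demo$primaryid
  for (nm in c("drug", "reac", "ther")) {
    if (!is.null(x[[nm]])) {
      x[[nm]] <- x[[nm]][x[[nm]]$primaryid %in% keep_pid, , drop = FALSE]
      rownames(x[[nm]]) <- NULL
    }
  }
  x
}

#' Identify cases reporting the focal drug
#'
#' Matches free-text drug names case-insensitively by substring against a
#' dictionary of name patterns (generic and trade names, with or without
#' biologic suffixes), restricted to the given FAERS role codes.
#'
#' @param drug A DRUG table (`data.frame` with `caseid`, `drugname`,
#'   `role_cod`).
#' @param dictionary Character vector of name patterns, e.g.
#'   `c("aducanumab", "aduhelm")`.
#' @param roles FAERS role codes to accept; default primary suspect only.
#' @return Sorted character vector of unique case ids.
#' @export
filter_focal_drug <- function(drug, dictionary, roles = "PS") {
  if (length(dictionary) == 0L || all(!nzchar(dictionary))) {
    stop_faers("drug dictionary must be non-empty", class = "faers_config_error")
  }
  if (!all(roles %in% c("PS", "SS", "C", "I"))) {
    stop_faers("roles must be FAERS codes PS/SS/C/I", class = "faers_config_error")
  }
  nm <- tolower(drug$drugname)
  hit <- rep(FALSE, length(nm))
  for (pat in tolower(dictionary)) {
    hit <- hit | grepl(pat, nm, fixed = TRUE)
  }
  hit <- hit & drug$role_cod %in% roles & !is.na(nm)
  sort(unique(as.character(drug$caseid[hit])))
}

#' Age-group assignment
#'
#' Converts an age with its FAERS unit code to years and bins it into the
#' groups used for reporting and stratification: `<18`, `18-44`, `45-64`,
#' `65-74`, `>=75`. Lower bounds are inclusive (an age of exactly 75 falls in
#' `>=75`). Missing ages map to `"unknown"`.
#'
#' @param age Numeric age values.
#' @param unit Unit per value: `"year"`/`"YR"`, `"month"`/`"MON"`,
#'   `"week"`/`"WK"`, `"day"`/`"DY"`, `"decade"`/`"DEC"`; `NA` assumes years.
#' @return Character vector of age groups.
#' @examples
#' assign_age_group(c(780, 64.9, 75), c("month", "year", "year"))
#' @export
assign_age_group <- function(age, unit = "year") {
  unit <- rep_len(ifelse(is.na(unit), "year", unit), length(age))
  fac <- c(year = 1, yr = 1, month = 1 / 12, mon = 1 / 12,
           week = 1 / 52.18, wk = 1 / 52.18, day = 1 / 365.25,
           dy = 1 / 365.25, decade = 10, dec = 10)
  f <- fac[tolower(unit)]
  if (any(is.na(f) & !is.na(age))) {
    stop_faers("unknown age unit: ",
               paste(unique(unit[is.na(f)]), collapse = ", "),
               class = "faers_value_error")
  }
  yrs <- age * f
  if (any(yrs < 0, na.rm = TRUE)) {
    stop_faers("negative age", class = "faers_value_error")
  }
  out <- as.character(cut(yrs, breaks = c(-Inf, 18, 45, 65, 75, Inf),
                          labels = c("<18", "18-44", "45-64", "65-74", ">=75"),
                          right = FALSE))
  out[is.na(out)] <- "unknown"
  out
}

age_in_years <- function(age, unit) {
  fac <- c(year = 1, yr = 1, month = 1 / 12, mon = 1 / 12,
           week = 1 / 52.18, wk = 1 / 52.18, day = 1 / 365.25,
           dy = 1 / 365.25, decade = 10, dec = 10)
  f <- fac[tolower(ifelse(is.na(unit), "year", unit))]
  age * f
}

#' Read a Preferred Term to System Organ Class mapping
#'
#' Two-column CSV (`pt,soc`). Each PT must map to exactly one SOC. The MedDRA
#' dictionary is licensed and is not bundled; a small synthetic stand-in
#' vocabulary ships with the package for testing (see
#' `system.file("extdata", "pt_soc_map_synthetic.csv", package = "faersignal")`).
#'
#' @param path CSV path.
#' @return `data.frame` with columns `pt` and `soc`.
#' @export
read_pt_soc_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(m) <- tolower(names(m))
  if (!all(c("pt", "soc") %in% names(m))) {
    stop_faers("PT-SOC map needs columns pt, soc", class = "faers_schema_error")
  }
  dup <- unique(m$pt[duplicated(m$pt)])
  bad <- dup[vapply(dup, function(p) length(unique(m$soc[m$pt == p])) > 1, TRUE)]
  if (length(bad) > 0L) {
    stop_faers("PT mapped to multiple SOCs: ", paste(bad, collapse = ", "),
               class = "faers_value_error")
  }
  unique(m[, c("pt", "soc")])
}
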