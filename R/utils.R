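# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_faers <- function(..., class) {
  stop(structure(
    class = c(class, "faersignal_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_counts <- function(a, b, c, d) {
  for (v in list(a, b, c, d)) {
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_faers("contingency counts must be finite and non-negative",
                 class = "faers_value_error")
    }
  }
  n <- unique(c(length(a), length(b), length(c), length(d)))
  if (length(n) != 1L) {
    stop_faers("a, b, c, d must have equal length", class = "faers_value_error")
  }
  invisible(TRUE)
}

# Deterministic per-stage seed derived from one root seed, so adding a stage
# upstream does not perturb the draws of the stages after it. Kept below 2^31.
substream_seed <- function(root, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(root) * 48271 + h) %% 2147483647)
}

round2 <- function(x) round(x, 2)

# yyyymmdd integer -> Date (NA-safe)
ymd_to_date <- function(x) {
  x <- suppressWarnings(as.integer(x))
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & x >= 10000101 & x <= 29991231
  out[ok] <- as.Date(sprintf("%08d", x[ok]), format = "%Y%m%d")
  out
}

date_to_ymd <- function(d) as.integer(format(d, "%Y%m%d"))
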