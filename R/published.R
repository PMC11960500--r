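#' Published aducanumab FAERS reference statistics
#'
#' Loads the published statistics bundled with the package, extracted from an
#' aducanumab pharmacovigilance analysis of FAERS (surveillance window
#' January 2004 - June 2024, 510 deduplicated reports, 1,095 drug-event
#' pairs, database event total 54,336,884):
#' \describe{
#'   \item{`"pt"`}{the 27 Preferred-Term level safety signals (case count,
#'     ROR with CI, PRR with chi-square, IC with IC-2SD, EBGM with EBGM05).}
#'   \item{`"soc"`}{the 22 System-Organ-Class level rows (report counting).}
#'   \item{`"demographics"`}{long-format demographic, onset-bin, weight and
#'     margin values (`category`, `level`, `value`).}
#' }
#' These printed values serve as calibration targets for the synthetic
#' generator and as inputs for [reconstruct_contingency()].
#'
#' @param which `"pt"`, `"soc"` or `"demographics"`.
#' @return A `data.frame`.
#' @export
published_reference <- function(which = c("pt", "soc", "demographics")) {
  which <- match.arg(which)
  f <- c(pt = "aducanumab_pt_signals.csv",
         soc = "aducanumab_soc_stats.csv",
         demographics = "aducanumab_demographics.csv")[[which]]
  path <- system.file("extdata", f, package = "faersignal")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled synthetic PT-to-SOC vocabulary
#'
#' A small stand-in mapping (42 Preferred Terms across 14 organ classes)
#' mirroring the organ-class structure of real adverse-event dictionaries.
#' The licensed MedDRA hierarchy is not bundled; this synthetic vocabulary
#' exists so every pipeline stage is testable.
#'
#' @return `data.frame` with columns `pt`, `soc`.
#' @export
synthetic_pt_soc_map <- function() {
  read_pt_soc_map(system.file("extdata", "pt_soc_map_synthetic.csv",
                              package = "faersignal"))
}
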