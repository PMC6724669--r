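#' Triage configuration
#'
#' Bundles every tunable threshold of the triage engine. Frequency thresholds
#' are allele fractions in `[0, 1]`; the germline frequency gate can be
#' disabled entirely by passing `max_af = NA` (or the string `"off"`).
#'
#' @param max_af Germline medal frequency gate applied to the ExAC non-TCGA
#'   allele frequency. Variants with a frequency strictly greater than this
#'   value receive no medal unless rescued by a curated-database exception.
#'   `NA` (or `"off"`) disables the gate.
#' @param pm2_max_af Ceiling for the PM2 evidence tag: PM2 is assigned when
#'   the ExAC non-TCGA frequency is absent or not greater than this value.
#' @param ba1_min_af Floor for the stand-alone benign BA1 tag: BA1 is assigned
#'   when the ExAC non-TCGA frequency is strictly greater than this value.
#' @param hotspot_min_tumors Minimum per-codon tumor count for a COSMIC record
#'   to qualify as a somatic hotspot.
#' @param clinvar_min_stars Minimum ClinVar review-status stars for a
#'   pathogenic/likely-pathogenic ClinVar match to count as highly curated
#'   (gold tier and frequency-gate rescue).
#' @param splice_window_donor Number of exonic bases at the donor (3') edge of
#'   an exon within which a silent/missense variant is promoted to
#'   `splice_region`.
#' @param splice_window_acceptor Same, for the acceptor (5') edge.
#' @param revel_damaging REVEL score at or above which a variant is considered
#'   predicted damaging.
#' @param min_damaging_calls Number of categorical algorithm calls required to
#'   call a variant predicted damaging. `NULL` (default) requires a strict
#'   majority of the non-unknown calls.
#' @param splice_region_truncating Whether a promoted `splice_region`
#'   consequence counts as truncating for the medal engine (default `FALSE`;
#'   only canonical `splice` does).
#' @return A list of class `triage_config`.
#' @examples
#' cfg <- triage_config()
#' cfg$max_af
#' triage_config(max_af = "off")$max_af   # gate disabled
#' @export
triage_config <- function(max_af = 0.001,
                          pm2_max_af = 1e-4,
                          ba1_min_af = 0.05,
                          hotspot_min_tumors = 10L,
                          clinvar_min_stars = 2L,
                          splice_window_donor = 3L,
                          splice_window_acceptor = 1L,
                          revel_damaging = 0.5,
                          min_damaging_calls = NULL,
                          splice_region_truncating = FALSE) {
  if (identical(max_af, "off")) max_af <- NA_real_
  max_af <- as.numeric(max_af)
  cfg <- list(
    max_af = max_af,
    pm2_max_af = as.numeric(pm2_max_af),
    ba1_min_af = as.numeric(ba1_min_af),
    hotspot_min_tumors = as.integer(hotspot_min_tumors),
    clinvar_min_stars = as.integer(clinvar_min_stars),
    splice_window_donor = as.integer(splice_window_donor),
    splice_window_acceptor = as.integer(splice_window_acceptor),
    revel_damaging = as.numeric(revel_damaging),
    min_damaging_calls = if (is.null(min_damaging_calls)) NULL else as.integer(min_damaging_calls),
    splice_region_truncating = isTRUE(splice_region_truncating)
  )
  for (f in c("pm2_max_af", "ba1_min_af")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("'%s' must be a frequency in [0, 1]", f))
    }
  }
  if (!is.na(cfg$max_af)) {
    if (cfg$max_af < 0 || cfg$max_af > 1) stop("'max_af' must be in [0, 1] or NA/'off'")
    if (!(cfg$pm2_max_af <= cfg$max_af && cfg$max_af <= cfg$ba1_min_af)) {
      stop("frequency thresholds must satisfy pm2_max_af <= max_af <= ba1_min_af")
    }
  }
  for (f in c("hotspot_min_tumors", "clinvar_min_stars",
              "splice_window_donor", "splice_window_acceptor")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stop(sprintf("'%s' must be an integer >= 0", f))
  }
  if (is.na(cfg$revel_damaging) || cfg$revel_damaging < 0 || cfg$revel_damaging > 1) {
    stop("'revel_damaging' must be in [0, 1]")
  }
  structure(cfg, class = "triage_config")
}

#' @export
print.triage_config <- function(x, ...) {
  cat("Triage configuration:\n")
  cat(sprintf("  frequency gate (ExAC non-TCGA): %s\n",
              if (is.na(x$max_af)) "disabled" else format(x$max_af)))
  cat(sprintf("  PM2 ceiling: %g   BA1 floor: %g\n", x$pm2_max_af, x$ba1_min_af))
  cat(sprintf("  COSMIC hotspot min tumors: %d   ClinVar min stars: %d\n",
              x$hotspot_min_tumors, x$clinvar_min_stars))
  cat(sprintf("  splice promotion window (donor/acceptor exonic bases): %d/%d\n",
              x$splice_window_donor, x$splice_window_acceptor))
  cat(sprintf("  REVEL damaging cutoff: %g\n", x$revel_damaging))
  invisible(x)
}
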