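GOLD_EXACT_SOURCES <- c("IARC_TP53", "ASU_TERT", "ARUP_MEN2", "NHGRI_BIC")
SILVER_EXACT_SOURCES <- c("BRCA_SHARE", "ALSOD", "LOVD_APC", "LOVD_MSH2", "RB1")

# medal tier of one matched curated record, ignoring its match grade:
# "gold", "silver" or NA (record carries no medal-relevant assertion).
# Presence suffices for the locus-specific databases unless the record
# carries an explicitly non-P/LP call; ClinVar requires P/LP and is split
# by review stars; committee records require P/LP.
.db_tier <- function(source, call, stars, cfg) {
  plp <- !is.na(call) && call %in% c("P", "LP")
  plp_or_absent <- is.na(call) || call %in% c("P", "LP")
  if (source == "IARC_TP53") return("gold")
  if (source %in% c("ASU_TERT", "ARUP_MEN2", "NHGRI_BIC")) {
    return(if (plp_or_absent) "gold" else NA_character_)
  }
  if (source == "COMMITTEE") return(if (plp) "gold" else NA_character_)
  if (source == "CLINVAR") {
    if (!plp) return(NA_character_)
    s <- if (is.na(stars)) 0L else stars
    return(if (s >= cfg$clinvar_min_stars) "gold" else "silver")
  }
  if (source %in% SILVER_EXACT_SOURCES) {
    return(if (plp_or_absent) "silver" else NA_character_)
  }
  NA_character_
}

.is_truncating <- function(consequence, cfg) {
  consequence %in% TRUNCATING ||
    (cfg$splice_region_truncating && consequence == "splice_region")
}

#' Aggregate in silico damage predictions
#'
#' A variant is predicted damaging when its REVEL score is at or above
#' `cfg$revel_damaging`, or when at least `cfg$min_damaging_calls`
#' categorical algorithm calls (default: a strict majority of the
#' non-unknown calls) say damaging. It is predicted tolerated when at least
#' one categorical call is present, all non-unknown calls say tolerated,
#' and REVEL (if present) is below the damaging cutoff. Otherwise the
#' aggregate is unknown.
#'
#' @param pred Prediction profile: list with `calls` (character vector over
#'   damaging/tolerated/unknown) and `revel` (numeric or `NA`).
#' @param cfg A [triage_config()].
#' @return One of `"damaging"`, `"tolerated"`, `"unknown"`.
#' @export
aggregate_prediction <- function(pred, cfg = triage_config()) {
  calls <- pred$calls[pred$calls %in% c("damaging", "tolerated")]
  n <- length(calls)
  nd <- sum(calls == "damaging")
  revel <- pred$revel
  if (length(revel) != 1L) revel <- NA_real_
  if (!is.na(revel) && revel >= cfg$revel_damaging) return("damaging")
  thr <- if (!is.null(cfg$min_damaging_calls)) {
    max(1L, cfg$min_damaging_calls)
  } else {
    n %/% 2L + 1L
  }
  if (n > 0L && nd >= thr) return("damaging")
  if (n > 0L && nd == 0L && (is.na(revel) || revel < cfg$revel_damaging)) {
    return("tolerated")
  }
  "unknown"
}

.medal_max <- function(medals) {
  if (!length(medals)) return("UNKNOWN")
  MEDALS[min(match(medals, MEDALS))]
}

#' Assign the germline triage medal
#'
#' Implements the tiered germline classification. Evaluation order:
#' blacklist (exact genomic match prevents any medal), whitelist (always
#' receives a medal; gold, the highest-trust source), the ExAC non-TCGA
#' frequency gate with its curated-database rescue exception, then the
#' medal rules with all fired rules recorded and the highest granted medal
#' winning. Gold: truncating consequence in a loss-of-function disease
#' gene; exact match to a highly curated database (IARC TP53, ClinVar P/LP
#' with enough review stars, ASU TERT, ARUP MEN2, NHGRI BIC, committee
#' P/LP); somatic hotspot (COSMIC count-thresholded or curated PCGP).
#' Silver: in-frame indel; truncating in a non-loss-of-function gene;
#' predicted damaging; exact match to a silver-tier database (ClinVar P/LP
#' below the star threshold, BRCA Share, ALSoD, LOVD APC/MSH2, RB1);
#' imperfect match (same position different allele, or same codon
#' different amino acid) to a gold-tier database. Bronze: predicted
#' tolerated; imperfect match to a silver-tier database. Otherwise
#' unknown. Once rescued by the frequency-gate exception, all rules apply.
#'
#' @param variant One-row variant data frame.
#' @param ann One-row selected (most severe) annotation.
#' @param pf Named frequency vector from [kb_frequencies()].
#' @param pred Prediction profile from [kb_predictions()].
#' @param kb A `knowledgebase`.
#' @param gene_meta One-row gene metadata (or `NULL`: treated as
#'   non-loss-of-function with a warning, never silently gold).
#' @param cfg A [triage_config()].
#' @param whitelist,blacklist Character vectors of exact variant keys.
#' @return An object of class `medal_result`: list with `medal`, `reasons`
#'   (data frame `rule_id`, `evidence`), `gate_status`, `matches`.
#' @export
assign_germline_medal <- function(variant, ann, pf, pred, kb, gene_meta,
                                  cfg = triage_config(),
                                  whitelist = character(0),
                                  blacklist = character(0)) {
  reasons <- data.frame(rule_id = character(0), evidence = character(0),
                        stringsAsFactors = FALSE)
  add <- function(rule_id, evidence) {
    rbind(reasons, data.frame(rule_id = rule_id, evidence = evidence,
                              stringsAsFactors = FALSE))
  }
  res <- function(medal, gate_status, matches = NULL) {
    structure(list(medal = medal, reasons = reasons,
                   gate_status = gate_status, matches = matches),
              class = "medal_result")
  }
  key <- variant$key
  if (key %in% blacklist) {
    reasons <- add("blacklist", key)
    return(res("UNKNOWN", "blacklisted"))
  }
  if (key %in% whitelist) {
    reasons <- add("whitelist", key)
    return(res("GOLD", "whitelisted"))
  }

  matches <- match_variant(kb, variant, gene = ann$gene, codon = ann$codon,
                           aa_ref = ann$p_aa_ref, aa_alt = ann$p_aa_alt)

  gate_status <- "passed"
  exac <- unname(pf[["exac_nontcga"]])
  if (!is.na(cfg$max_af) && !is.na(exac) && exac > cfg$max_af) {
    exc <- frequency_gate_exception(matches, cfg)
    if (!exc$rescued) {
      reasons <- add("frequency_gate",
                     sprintf("ExAC non-TCGA frequency %g > %g", exac, cfg$max_af))
      return(res("UNKNOWN", "failed_frequency", matches))
    }
    gate_status <- "rescued_by_exception"
    reasons <- add("frequency_gate_exception", exc$reason)
  }

  if (is.null(gene_meta) || nrow(gene_meta) == 0L) {
    warning(sprintf("no gene metadata for '%s'; treated as non-loss-of-function",
                    ann$gene))
    lof <- FALSE
  } else {
    lof <- isTRUE(gene_meta$is_lof_gene[1L])
  }
  trunc <- .is_truncating(ann$consequence, cfg)
  agg <- aggregate_prediction(pred, cfg)
  hs <- is_hotspot(kb, ann$gene, ann$codon, cfg)

  fired <- character(0)
  if (trunc && lof) {
    fired <- c(fired, "GOLD")
    reasons <- add("gold_truncating_lof",
                   sprintf("%s in loss-of-function gene %s", ann$consequence, ann$gene))
  }
  if (hs$is_hotspot) {
    fired <- c(fired, "GOLD")
    reasons <- add("gold_hotspot",
                   sprintf("%s hotspot at %s codon %d (%d tumors)",
                           hs$record$source, ann$gene, ann$codon,
                           hs$record$tumor_count))
  }
  if (nrow(matches)) {
    for (j in seq_len(nrow(matches))) {
      m <- matches[j, ]
      tier <- .db_tier(m$source, m$call, m$stars, cfg)
      if (is.na(tier)) next
      exact <- m$grade %in% c("EXACT_GENOMIC", "EXACT_PROTEIN")
      if (exact && tier == "gold") {
        fired <- c(fired, "GOLD")
        reasons <- add("gold_db_match", sprintf("%s (%s)", m$source, m$grade))
      } else if (exact && tier == "silver") {
        fired <- c(fired, "SILVER")
        reasons <- add("silver_db_match", sprintf("%s (%s)", m$source, m$grade))
      } else if (!exact && tier == "gold") {
        fired <- c(fired, "SILVER")
        reasons <- add("silver_imperfect_gold_db",
                       sprintf("%s (%s)", m$source, m$grade))
      } else if (!exact && tier == "silver") {
        fired <- c(fired, "BRONZE")
        reasons <- add("bronze_imperfect_silver_db",
                       sprintf("%s (%s)", m$source, m$grade))
      }
    }
  }
  if (ann$consequence == "inframe_indel") {
    fired <- c(fired, "SILVER")
    reasons <- add("silver_inframe_indel", "in-frame indel")
  }
  if (trunc && !lof) {
    fired <- c(fired, "SILVER")
    reasons <- add("silver_truncating_non_lof",
                   sprintf("%s in non-loss-of-function gene %s",
                           ann$consequence, ann$gene))
  }
  if (agg == "damaging") {
    fired <- c(fired, "SILVER")
    reasons <- add("silver_predicted_damaging", "predicted damaging in silico")
  }
  if (agg == "tolerated") {
    fired <- c(fired, "BRONZE")
    reasons <- add("bronze_predicted_tolerated", "predicted tolerated in silico")
  }
  res(.medal_max(fired), gate_status, matches)
}

#' Assign the somatic triage medal
#'
#' A separate, simpler classification considering the variant in a
#' somatically acquired context: only the somatic resources (COSMIC and
#' PCGP hotspot tables), loss-of-function logic and in silico predictions
#' are consulted; germline-only resources (ClinVar, IARC TP53, the locus
#' databases) never are. Gold for a hotspot match (the observed amino-acid
#' changes, when recorded, include this variant's) or a truncating variant
#' in a loss-of-function gene; silver for an imperfect hotspot match (same
#' codon, different amino acid observed) or predicted damaging; bronze for
#' predicted tolerated; unknown otherwise.
#'
#' @inheritParams assign_germline_medal
#' @return List with `medal` and `reasons`.
#' @export
assign_somatic_medal <- function(variant, ann, pred, kb, gene_meta,
                                 cfg = triage_config()) {
  reasons <- data.frame(rule_id = character(0), evidence = character(0),
                        stringsAsFactors = FALSE)
  add <- function(rule_id, evidence) {
    rbind(reasons, data.frame(rule_id = rule_id, evidence = evidence,
                              stringsAsFactors = FALSE))
  }
  lof <- !is.null(gene_meta) && nrow(gene_meta) > 0L &&
    isTRUE(gene_meta$is_lof_gene[1L])
  trunc <- .is_truncating(ann$consequence, cfg)
  agg <- aggregate_prediction(pred, cfg)
  hs <- is_hotspot(kb, ann$gene, ann$codon, cfg)

  fired <- character(0)
  if (hs$is_hotspot) {
    aas <- strsplit(ifelse(is.na(hs$record$aa_changes), "",
                           hs$record$aa_changes), ",", fixed = TRUE)[[1L]]
    aas <- trimws(aas[nzchar(aas)])
    exact <- length(aas) == 0L || (!is.na(ann$p_aa_alt) && ann$p_aa_alt %in% aas)
    if (exact) {
      fired <- c(fired, "GOLD")
      reasons <- add("somatic_gold_hotspot",
                     sprintf("%s hotspot at %s codon %d",
                             hs$record$source, ann$gene, ann$codon))
    } else {
      fired <- c(fired, "SILVER")
      reasons <- add("somatic_silver_imperfect_hotspot",
                     sprintf("%s hotspot at %s codon %d, different amino acid",
                             hs$record$source, ann$gene, ann$codon))
    }
  }
  if (trunc && lof) {
    fired <- c(fired, "GOLD")
    reasons <- add("somatic_gold_truncating_lof",
                   sprintf("%s in loss-of-function gene %s",
                           ann$consequence, ann$gene))
  }
  if (agg == "damaging") {
    fired <- c(fired, "SILVER")
    reasons <- add("somatic_silver_predicted_damaging",
                   "predicted damaging in silico")
  }
  if (agg == "tolerated") {
    fired <- c(fired, "BRONZE")
    reasons <- add("somatic_bronze_predicted_tolerated",
                   "predicted tolerated in silico")
  }
  list(medal = .medal_max(fired), reasons = reasons)
}

#' @export
print.medal_result <- function(x, ...) {
  cat(sprintf("Medal: %s (gate: %s)\n", x$medal, x$gate_status))
  if (nrow(x$reasons)) {
    for (i in seq_len(nrow(x$reasons))) {
      cat(sprintf("  - %s: %s\n", x$reasons$rule_id[i], x$reasons$evidence[i]))
    }
  } else {
    cat("  (no rules fired)\n")
  }
  invisible(x)
}
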