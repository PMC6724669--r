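# Independent decision-table transcriptions of the triage and combining
# rules. These operate on precomputed evidence feature flags, never on the
# knowledgebase or the annotation machinery, and are what the fixture
# generator uses to compute expected results for its manifest: the engines
# under test are never consulted when a manifest is built.

#' Decision-table oracle for the germline medal
#'
#' Maps a flat set of evidence feature flags straight onto the tier
#' diagram, independently of the medal engine.
#'
#' @param f A list or one-row data frame with logical fields `blacklisted`,
#'   `whitelisted`, `rescue_available`, `truncating`, `lof`,
#'   `exact_gold_db`, `exact_silver_db`, `imperfect_gold_db`,
#'   `imperfect_silver_db`, `hotspot`, `inframe`; numeric `exac` (`NA` =
#'   absent); character `pred` over damaging/tolerated/unknown.
#' @param cfg A [triage_config()].
#' @return List with `medal` and `gate_status`.
#' @export
oracle_germline_medal <- function(f, cfg = triage_config()) {
  if (isTRUE(f$blacklisted)) return(list(medal = "UNKNOWN", gate_status = "blacklisted"))
  if (isTRUE(f$whitelisted)) return(list(medal = "GOLD", gate_status = "whitelisted"))
  gate <- "passed"
  if (!is.na(cfg$max_af) && !is.na(f$exac) && f$exac > cfg$max_af) {
    if (!isTRUE(f$rescue_available)) {
      return(list(medal = "UNKNOWN", gate_status = "failed_frequency"))
    }
    gate <- "rescued_by_exception"
  }
  gold <- (isTRUE(f$truncating) && isTRUE(f$lof)) ||
    isTRUE(f$exact_gold_db) || isTRUE(f$hotspot)
  silver <- isTRUE(f$inframe) ||
    (isTRUE(f$truncating) && !isTRUE(f$lof)) ||
    identical(f$pred, "damaging") ||
    isTRUE(f$exact_silver_db) || isTRUE(f$imperfect_gold_db)
  bronze <- identical(f$pred, "tolerated") || isTRUE(f$imperfect_silver_db)
  medal <- if (gold) "GOLD" else if (silver) "SILVER" else if (bronze) "BRONZE" else "UNKNOWN"
  list(medal = medal, gate_status = gate)
}

#' Decision-table oracle for the somatic medal
#'
#' @param f Feature flags as in [oracle_germline_medal()], plus
#'   `hotspot_aa_match` (the hotspot's observed amino-acid changes include
#'   this variant's, or are unrecorded).
#' @param cfg A [triage_config()].
#' @return The somatic medal.
#' @export
oracle_somatic_medal <- function(f, cfg = triage_config()) {
  gold <- (isTRUE(f$hotspot) && isTRUE(f$hotspot_aa_match)) ||
    (isTRUE(f$truncating) && isTRUE(f$lof))
  silver <- (isTRUE(f$hotspot) && !isTRUE(f$hotspot_aa_match)) ||
    identical(f$pred, "damaging")
  bronze <- identical(f$pred, "tolerated")
  if (gold) "GOLD" else if (silver) "SILVER" else if (bronze) "BRONZE" else "UNKNOWN"
}

#' Feature-flag oracle for the automated ACMG tags
#'
#' @param f Feature flags: `truncating`, `lof`, `cosmic_hotspot`, `exac`,
#'   `inframe`, `exact_plp_clinvar_committee`, `same_codon_plp`.
#' @param cfg A [triage_config()].
#' @return Character vector of expected auto tag codes.
#' @export
oracle_auto_tags <- function(f, cfg = triage_config()) {
  tags <- character(0)
  if (isTRUE(f$truncating) && isTRUE(f$lof)) tags <- c(tags, "PVS1")
  if (isTRUE(f$cosmic_hotspot)) tags <- c(tags, "PM1")
  if (is.na(f$exac) || f$exac <= cfg$pm2_max_af) {
    tags <- c(tags, "PM2")
  } else if (f$exac > cfg$ba1_min_af) {
    tags <- c(tags, "BA1")
  }
  if (isTRUE(f$inframe)) tags <- c(tags, "PM4")
  if (isTRUE(f$exact_plp_clinvar_committee)) tags <- c(tags, "PS1")
  if (isTRUE(f$same_codon_plp)) tags <- c(tags, "PM5")
  tags
}

#' Brute-force oracle for the five-tier ACMG combining rules
#'
#' Direct boolean transcription of the combining rules, written without
#' reference to the shipped rule table that [classify_acmg()] evaluates.
#'
#' @param codes Character vector of ACMG codes.
#' @return One of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @export
oracle_classify <- function(codes) {
  codes <- unique(codes)
  npvs <- sum(codes == "PVS1")
  nps <- sum(codes %in% paste0("PS", 1:4))
  npm <- sum(codes %in% paste0("PM", 1:6))
  npp <- sum(codes %in% paste0("PP", 1:5))
  nba <- sum(codes == "BA1")
  nbs <- sum(codes %in% paste0("BS", 1:4))
  nbp <- sum(codes %in% paste0("BP", 1:7))
  path <- (npvs >= 1 && (nps >= 1 || npm >= 2 || (npm >= 1 && npp >= 1) || npp >= 2)) ||
    nps >= 2 ||
    (nps >= 1 && (npm >= 3 || (npm >= 2 && npp >= 2) || (npm >= 1 && npp >= 4)))
  lp <- (npvs >= 1 && npm >= 1) ||
    (nps >= 1 && npm >= 1) ||
    (nps >= 1 && npp >= 2) ||
    npm >= 3 ||
    (npm >= 2 && npp >= 2) ||
    (npm >= 1 && npp >= 4)
  ben <- nba >= 1 || nbs >= 2
  lb <- (nbs >= 1 && nbp >= 1) || nbp >= 2
  pside <- path || lp
  bside <- ben || lb
  if (pside && bside) return("VUS")
  if (path) return("P")
  if (lp) return("LP")
  if (ben) return("B")
  if (lb) return("LB")
  "VUS"
}
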