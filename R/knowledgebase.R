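CURATED_SOURCES <- c("CLINVAR", "IARC_TP53", "ASU_TERT", "ARUP_MEN2",
                     "NHGRI_BIC", "BRCA_SHARE", "ALSOD", "LOVD_APC",
                     "LOVD_MSH2", "RB1", "COMMITTEE")
HOTSPOT_SOURCES <- c("COSMIC", "PCGP")
FREQ_SOURCES <- c("exac_nontcga", "esp", "kg1000", "pcgp")
MATCH_GRADES <- c("EXACT_GENOMIC", "EXACT_PROTEIN", "SAME_POSITION_DIFF_ALLELE",
                  "SAME_CODON_DIFF_AA", "NONE")
# numeric rank: higher is more specific
.grade_rank <- c(EXACT_GENOMIC = 4, EXACT_PROTEIN = 3,
                 SAME_POSITION_DIFF_ALLELE = 2, SAME_CODON_DIFF_AA = 1, NONE = 0)

KB_SCHEMAS <- list(
  curated = c("source", "chrom", "pos", "ref", "alt", "gene",
              "protein_change", "call", "stars", "pubmed_ids"),
  hotspots = c("source", "gene", "codon", "tumor_count", "aa_changes",
               "curated_flag"),
  frequencies = c("chrom", "pos", "ref", "alt", FREQ_SOURCES),
  predictions = c("chrom", "pos", "ref", "alt", "algorithm", "call", "revel")
)

.read_kb_file <- function(path, what) {
  # everything as character: "T" is an allele, not a logical
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", na.strings = c("NA", ""),
                          colClasses = "character")
  unknown <- setdiff(names(df), KB_SCHEMAS[[what]])
  if (length(unknown)) {
    stop(sprintf("unknown column '%s' in %s", unknown[1L], basename(path)))
  }
  miss <- setdiff(KB_SCHEMAS[[what]], names(df))
  if (length(miss)) {
    stop(sprintf("missing column '%s' in %s", miss[1L], basename(path)))
  }
  df
}

.kb_genomic_key <- function(chrom, pos, ref, alt) {
  # normalized keys so snapshot rows match VCF-derived keys
  ok <- !is.na(chrom) & !is.na(pos) & !is.na(ref) & !is.na(alt)
  key <- rep(NA_character_, length(chrom))
  if (any(ok)) {
    v <- genomic_variant(chrom[ok], pos[ok], ref[ok], alt[ok])
    v <- normalize_variant(v)
    key[ok] <- v$key
  }
  key
}

#' Load a knowledgebase snapshot directory
#'
#' Reads any subset of the four tab-delimited snapshot files —
#' `curated.tsv` (curated variant databases with pathogenicity calls and
#' ClinVar review stars), `hotspots.tsv` (somatic hotspot codons with
#' pre-aggregated tumor counts), `frequencies.tsv` (population allele
#' frequencies) and `predictions.tsv` (in silico damage predictions and
#' REVEL scores) — builds lookup indices, and records a manifest of
#' per-file row counts together with the snapshot label, which is attached
#' to every output row because classifications drift with database versions.
#'
#' Pathogenicity calls are standardized via [standardize_pathogenicity()]
#' and protein notations parsed via [parse_protein_change()] at load time.
#' Unknown columns are an error naming the file and column; duplicated
#' `(source, genomic_key)` curated rows keep the last with a warning.
#'
#' @param dir Snapshot directory.
#' @param label Snapshot label (defaults to the directory name).
#' @return An object of class `knowledgebase`.
#' @export
load_snapshot <- function(dir, label = basename(normalizePath(dir))) {
  if (!dir.exists(dir)) stop(sprintf("snapshot directory not found: %s", dir))
  kb <- list(curated = NULL, hotspots = NULL, frequencies = NULL,
             predictions = NULL, manifest = list(), label = label,
             n_duplicate_curated = 0L)

  f <- file.path(dir, "curated.tsv")
  if (file.exists(f)) {
    cu <- .read_kb_file(f, "curated")
    bad_src <- !cu$source %in% CURATED_SOURCES
    if (any(bad_src)) stop(sprintf("unknown curated source: %s", cu$source[bad_src][1L]))
    cu$pos <- as.integer(cu$pos)
    cu$stars <- as.integer(cu$stars)
    if (any(!is.na(cu$stars) & (cu$stars < 0L | cu$stars > 4L))) {
      stop("curated.tsv: 'stars' must be between 0 and 4")
    }
    if (any(!is.na(cu$stars) & cu$source != "CLINVAR")) {
      stop("curated.tsv: 'stars' may be present only for CLINVAR records")
    }
    cu$call_std <- ifelse(is.na(cu$call), NA_character_,
                          standardize_pathogenicity(cu$call))
    pp <- parse_protein_change(ifelse(is.na(cu$protein_change), "",
                                      cu$protein_change))
    cu$p_aa_ref <- pp$aa_ref; cu$p_codon <- pp$codon
    cu$p_aa_alt <- pp$aa_alt; cu$p_status <- pp$status
    cu$genomic_key <- .kb_genomic_key(canonical_chrom(cu$chrom), cu$pos,
                                      cu$ref, cu$alt)
    has_protein <- !is.na(cu$gene) & !is.na(cu$p_codon)
    if (any(is.na(cu$genomic_key) & !has_protein)) {
      stop("curated.tsv: every record needs a genomic key or gene + protein change")
    }
    kp <- parse_variant_key(cu$genomic_key[!is.na(cu$genomic_key)])
    cu$chrompos <- NA_character_
    cu$chrompos[!is.na(cu$genomic_key)] <- paste0(kp$chrom, ":", kp$pos)
    dup <- duplicated(paste(cu$source, cu$genomic_key),
                      fromLast = TRUE) & !is.na(cu$genomic_key)
    if (any(dup)) {
      warning(sprintf("curated.tsv: %d duplicate (source, genomic_key) row(s); last wins",
                      sum(dup)))
      kb$n_duplicate_curated <- sum(dup)
      cu <- cu[!dup, , drop = FALSE]
    }
    cu$record_id <- seq_len(nrow(cu))
    kb$curated <- cu
    kb$manifest$curated <- nrow(cu)
  }

  f <- file.path(dir, "hotspots.tsv")
  if (file.exists(f)) {
    hs <- .read_kb_file(f, "hotspots")
    if (any(!hs$source %in% HOTSPOT_SOURCES)) stop("hotspots.tsv: unknown source")
    hs$codon <- as.integer(hs$codon)
    hs$tumor_count <- as.integer(hs$tumor_count)
    if (any(is.na(hs$tumor_count) | hs$tumor_count < 1L)) {
      stop("hotspots.tsv: 'tumor_count' must be an integer >= 1")
    }
    if (anyDuplicated(hs[, c("source", "gene", "codon")])) {
      stop("hotspots.tsv: (source, gene, codon) must be unique")
    }
    hs$curated_flag <- tolower(as.character(hs$curated_flag)) %in%
      c("1", "true", "t", "yes")
    kb$hotspots <- hs
    kb$manifest$hotspots <- nrow(hs)
  }

  f <- file.path(dir, "frequencies.tsv")
  if (file.exists(f)) {
    fr <- .read_kb_file(f, "frequencies")
    for (s in FREQ_SOURCES) {
      fr[[s]] <- as.numeric(fr[[s]])
      if (any(!is.na(fr[[s]]) & (fr[[s]] < 0 | fr[[s]] > 1))) {
        stop(sprintf("frequencies.tsv: '%s' must be in [0, 1]", s))
      }
    }
    fr$genomic_key <- .kb_genomic_key(canonical_chrom(fr$chrom),
                                      as.integer(fr$pos), fr$ref, fr$alt)
    kb$frequencies <- fr
    kb$manifest$frequencies <- nrow(fr)
  }

  f <- file.path(dir, "predictions.tsv")
  if (file.exists(f)) {
    pr <- .read_kb_file(f, "predictions")
    pr$revel <- as.numeric(pr$revel)
    if (any(!is.na(pr$revel) & (pr$revel < 0 | pr$revel > 1))) {
      stop("predictions.tsv: 'revel' must be in [0, 1]")
    }
    ok_call <- is.na(pr$call) | pr$call %in% c("damaging", "tolerated", "unknown")
    if (!all(ok_call)) stop("predictions.tsv: 'call' must be damaging/tolerated/unknown")
    pr$genomic_key <- .kb_genomic_key(canonical_chrom(pr$chrom),
                                      as.integer(pr$pos), pr$ref, pr$alt)
    kb$predictions <- pr
    kb$manifest$predictions <- nrow(pr)
  }

  structure(kb, class = "knowledgebase")
}

#' Write a knowledgebase back to snapshot files
#'
#' Inverse of [load_snapshot()] (used for round-trip stability checks and
#' snapshot re-versioning). Only the original schema columns are written.
#'
#' @param kb A `knowledgebase`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_snapshot <- function(kb, dir) {
  stopifnot(inherits(kb, "knowledgebase"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, what) {
    utils::write.table(df[, KB_SCHEMAS[[what]], drop = FALSE],
                       file.path(dir, paste0(what, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  if (!is.null(kb$curated)) wr(kb$curated, "curated")
  if (!is.null(kb$hotspots)) {
    hs <- kb$hotspots
    hs$curated_flag <- as.integer(hs$curated_flag)
    wr(hs, "hotspots")
  }
  if (!is.null(kb$frequencies)) wr(kb$frequencies, "frequencies")
  if (!is.null(kb$predictions)) wr(kb$predictions, "predictions")
  invisible(dir)
}

#' @export
print.knowledgebase <- function(x, ...) {
  cat(sprintf("Knowledgebase snapshot '%s'\n", x$label))
  for (nm in names(x$manifest)) cat(sprintf("  %s: %d rows\n", nm, x$manifest[[nm]]))
  invisible(x)
}

#' Match a variant against curated records at graded specificity
#'
#' Every curated record sharing the variant's genomic position or its
#' (gene, codon) is returned with its best applicable match grade, ordered
#' `EXACT_GENOMIC > EXACT_PROTEIN > SAME_POSITION_DIFF_ALLELE >
#' SAME_CODON_DIFF_AA`. Protein-level matching requires the same gene and
#' codon number but not the same transcript (locus databases rarely state
#' transcripts); `EXACT_PROTEIN` additionally requires the same alternate
#' amino acid.
#'
#' @param kb A `knowledgebase`.
#' @param variant One-row variant data frame (needs `chrom`, `pos`, `key`).
#' @param gene Gene symbol of the annotation under evaluation.
#' @param codon Codon number or `NA`.
#' @param aa_ref,aa_alt One-letter amino acids of the change, or `NA`.
#' @return Data frame of matched records (`source`, `grade`, `call`
#'   (standardized), `stars`, `genomic_key`, `protein_change`, `pubmed_ids`,
#'   `record_id`), ordered by source then decreasing grade.
#' @export
match_variant <- function(kb, variant, gene, codon = NA_integer_,
                          aa_ref = NA_character_, aa_alt = NA_character_) {
  empty <- data.frame(source = character(0), grade = character(0),
                      call = character(0), stars = integer(0),
                      genomic_key = character(0), protein_change = character(0),
                      pubmed_ids = character(0), record_id = integer(0),
                      stringsAsFactors = FALSE)
  cu <- kb$curated
  if (is.null(cu) || nrow(cu) == 0L) return(empty)
  chrompos <- paste0(variant$chrom, ":", variant$pos)
  cand <- which(
    (!is.na(cu$chrompos) & cu$chrompos == chrompos) |
      (!is.na(cu$gene) & !is.na(cu$p_codon) & !is.na(codon) &
         cu$gene == gene & cu$p_codon == codon))
  if (!length(cand)) return(empty)
  grade <- character(length(cand))
  for (j in seq_along(cand)) {
    rec <- cu[cand[j], ]
    g <- "NONE"
    if (!is.na(rec$genomic_key) && rec$genomic_key == variant$key) {
      g <- "EXACT_GENOMIC"
    } else if (!is.na(rec$gene) && !is.na(rec$p_codon) && !is.na(codon) &&
               rec$gene == gene && rec$p_codon == codon &&
               !is.na(rec$p_aa_alt) && !is.na(aa_alt) &&
               rec$p_aa_alt == aa_alt &&
               (is.na(rec$p_aa_ref) || is.na(aa_ref) || rec$p_aa_ref == aa_ref)) {
      g <- "EXACT_PROTEIN"
    } else if (!is.na(rec$chrompos) && rec$chrompos == chrompos) {
      g <- "SAME_POSITION_DIFF_ALLELE"
    } else if (!is.na(rec$gene) && !is.na(rec$p_codon) && !is.na(codon) &&
               rec$gene == gene && rec$p_codon == codon) {
      g <- "SAME_CODON_DIFF_AA"
    }
    grade[j] <- g
  }
  keep <- grade != "NONE"
  cand <- cand[keep]; grade <- grade[keep]
  if (!length(cand)) return(empty)
  out <- data.frame(source = cu$source[cand], grade = grade,
                    call = cu$call_std[cand], stars = cu$stars[cand],
                    genomic_key = cu$genomic_key[cand],
                    protein_change = cu$protein_change[cand],
                    pubmed_ids = cu$pubmed_ids[cand],
                    record_id = cu$record_id[cand],
                    stringsAsFactors = FALSE)
  out[order(out$source, -.grade_rank[out$grade], out$record_id), , drop = FALSE]
}

#' Somatic hotspot determination
#'
#' A (gene, codon) is a hotspot iff a COSMIC record there has a tumor count
#' of at least `cfg$hotspot_min_tumors`, or a PCGP record there carries the
#' curated-hotspot flag (PCGP hotspots are curated, not count-thresholded).
#'
#' @param kb A `knowledgebase`.
#' @param gene Gene symbol.
#' @param codon Codon number.
#' @param cfg A [triage_config()].
#' @return List with `is_hotspot` (logical), `record` (the best qualifying
#'   record, or `NULL`) and `cosmic` (logical: a COSMIC record qualifies).
#' @export
is_hotspot <- function(kb, gene, codon, cfg = triage_config()) {
  no <- list(is_hotspot = FALSE, record = NULL, cosmic = FALSE)
  hs <- kb$hotspots
  if (is.null(hs) || is.na(codon)) return(no)
  rows <- hs[hs$gene == gene & hs$codon == codon, , drop = FALSE]
  if (!nrow(rows)) return(no)
  qual <- (rows$source == "COSMIC" & rows$tumor_count >= cfg$hotspot_min_tumors) |
    (rows$source == "PCGP" & rows$curated_flag)
  if (!any(qual)) return(no)
  rows <- rows[qual, , drop = FALSE]
  best <- rows[which.max(rows$tumor_count), , drop = FALSE]
  list(is_hotspot = TRUE, record = best, cosmic = any(rows$source == "COSMIC"))
}

#' Frequency-gate rescue exception
#'
#' A variant exceeding the population-frequency gate may still be classified
#' if it has an exact (genomic or protein) match to the IARC TP53 database,
#' or to a ClinVar record called pathogenic/likely pathogenic with a review
#' status of at least `cfg$clinvar_min_stars` gold stars. This retains
#' pathogenic founder variants and alleles with partial penetrance.
#'
#' @param matches Match table from [match_variant()].
#' @param cfg A [triage_config()].
#' @return List with `rescued` (logical) and `reason` (character).
#' @export
frequency_gate_exception <- function(matches, cfg = triage_config()) {
  if (nrow(matches) == 0L) return(list(rescued = FALSE, reason = NA_character_))
  exact <- matches$grade %in% c("EXACT_GENOMIC", "EXACT_PROTEIN")
  iarc <- exact & matches$source == "IARC_TP53"
  clinvar <- exact & matches$source == "CLINVAR" &
    !is.na(matches$call) & matches$call %in% c("P", "LP") &
    !is.na(matches$stars) & matches$stars >= cfg$clinvar_min_stars
  if (any(iarc)) return(list(rescued = TRUE, reason = "exact match in IARC TP53"))
  if (any(clinvar)) {
    return(list(rescued = TRUE,
                reason = sprintf("exact ClinVar P/LP match with >= %d stars",
                                 cfg$clinvar_min_stars)))
  }
  list(rescued = FALSE, reason = NA_character_)
}

#' Look up population allele frequencies for a variant key
#'
#' Absence means "not observed" and is distinct from 0.0 only in provenance;
#' both satisfy absent-or-rare predicates.
#'
#' @param kb A `knowledgebase`.
#' @param key A `"chrom:pos:ref>alt"` key.
#' @return Named numeric vector over `exac_nontcga`, `esp`, `kg1000`,
#'   `pcgp` (`NA` = absent).
#' @export
kb_frequencies <- function(kb, key) {
  out <- stats::setNames(rep(NA_real_, length(FREQ_SOURCES)), FREQ_SOURCES)
  fr <- kb$frequencies
  if (is.null(fr)) return(out)
  i <- which(fr$genomic_key == key)
  if (!length(i)) return(out)
  i <- i[length(i)]
  for (s in FREQ_SOURCES) out[[s]] <- fr[[s]][i]
  out
}

#' Look up the in silico prediction profile for a variant key
#'
#' @param kb A `knowledgebase`.
#' @param key A `"chrom:pos:ref>alt"` key.
#' @return List with `calls` (character vector of categorical algorithm
#'   calls) and `revel` (numeric score or `NA`).
#' @export
kb_predictions <- function(kb, key) {
  pr <- kb$predictions
  if (is.null(pr)) return(list(calls = character(0), revel = NA_real_))
  rows <- pr[!is.na(pr$genomic_key) & pr$genomic_key == key, , drop = FALSE]
  calls <- rows$call[!is.na(rows$call)]
  revel <- rows$revel[!is.na(rows$revel)]
  list(calls = calls,
       revel = if (length(revel)) max(revel) else NA_real_)
}
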