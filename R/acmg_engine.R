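ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4),
                paste0("PM", 1:6),
                paste0("PP", 1:5),
                "BA1",
                paste0("BS", 1:4),
                paste0("BP", 1:7))

#' Strength class of ACMG evidence codes
#'
#' Strength is fixed by the code prefix: PVS very strong, PS strong,
#' PM moderate, PP supporting, BA stand-alone benign, BS strong benign,
#' BP supporting benign.
#'
#' @param code Character vector of ACMG codes.
#' @return Character vector of strength classes.
#' @export
acmg_strength <- function(code) {
  bad <- !code %in% ACMG_CODES
  if (any(bad)) stop(sprintf("unknown ACMG code: %s", code[bad][1L]))
  prefix <- sub("[0-9]+$", "", code)
  unname(c(PVS = "very_strong", PS = "strong", PM = "moderate",
           PP = "supporting", BA = "stand_alone_benign",
           BS = "strong_benign", BP = "supporting_benign")[prefix])
}

#' Construct an ACMG evidence tag
#'
#' @param code One of the 28 ACMG criteria codes.
#' @param origin `"auto"` or `"manual"`.
#' @param pubmed_ids Character vector of supporting PubMed IDs.
#' @param note Free-text note.
#' @return One-row data frame (`code`, `strength`, `origin`, `pubmed_ids`
#'   comma-joined, `note`).
#' @export
acmg_tag <- function(code, origin = c("manual", "auto"),
                     pubmed_ids = character(0), note = "") {
  origin <- match.arg(origin)
  data.frame(code = code, strength = acmg_strength(code), origin = origin,
             pubmed_ids = paste(pubmed_ids, collapse = ","), note = note,
             stringsAsFactors = FALSE)
}

.empty_tags <- function() {
  data.frame(code = character(0), strength = character(0),
             origin = character(0), pubmed_ids = character(0),
             note = character(0), stringsAsFactors = FALSE)
}

.acmg_env <- new.env(parent = emptyenv())

.load_acmg_rules <- function() {
  if (!is.null(.acmg_env$rules)) return(.acmg_env$rules)
  path <- system.file("extdata", "acmg_combining_rules.tsv", package = "varmedal")
  rules <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             comment.char = "#")
  stopifnot(identical(names(rules),
                      c("outcome", "pvs", "ps", "pm", "pp", "ba", "bs", "bp")))
  .acmg_env$rules <- rules
  rules
}

#' Five-tier classification from a set of ACMG evidence codes
#'
#' Applies the published ACMG/AMP combining rules, shipped as a
#' human-reviewable rule table (`inst/extdata/acmg_combining_rules.tsv`):
#' each row lists the minimum tag counts per strength class for one
#' outcome. The pathogenic side takes the strongest fired outcome (P over
#' LP), the benign side likewise (B over LB); if both sides fire, or
#' neither does, the classification is VUS (strictest reading of the
#' conflict clause). `BA1` alone is stand-alone benign.
#'
#' @param codes Character vector of ACMG codes (each counted once).
#' @return One of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @examples
#' classify_acmg(c("PVS1", "PM2"))   # LP
#' classify_acmg("BA1")              # B
#' classify_acmg(character(0))       # VUS
#' @export
classify_acmg <- function(codes) {
  codes <- unique(as.character(codes))
  bad <- !codes %in% ACMG_CODES
  if (any(bad)) stop(sprintf("unknown ACMG code: %s", codes[bad][1L]))
  counts <- c(
    pvs = sum(codes == "PVS1"),
    ps = sum(grepl("^PS[0-9]$", codes)),
    pm = sum(grepl("^PM[0-9]$", codes)),
    pp = sum(grepl("^PP[0-9]$", codes)),
    ba = sum(codes == "BA1"),
    bs = sum(grepl("^BS[0-9]$", codes)),
    bp = sum(grepl("^BP[0-9]$", codes)))
  rules <- .load_acmg_rules()
  fires <- vapply(seq_len(nrow(rules)), function(i) {
    all(counts >= unlist(rules[i, c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")]))
  }, logical(1L))
  fired <- rules$outcome[fires]
  path_side <- if ("P" %in% fired) "P" else if ("LP" %in% fired) "LP" else NA
  ben_side <- if ("B" %in% fired) "B" else if ("LB" %in% fired) "LB" else NA
  if (!is.na(path_side) && !is.na(ben_side)) return("VUS")
  if (!is.na(path_side)) return(path_side)
  if (!is.na(ben_side)) return(ben_side)
  "VUS"
}

#' Auto-generate ACMG evidence tags for a variant
#'
#' Implements the automated subset of the ACMG criteria: PVS1 (truncating
#' variant in a loss-of-function disease gene), PM1 (COSMIC somatic
#' hotspot), PM2 (absent from ExAC non-TCGA or at a frequency not greater
#' than `cfg$pm2_max_af`), BA1 (ExAC non-TCGA frequency greater than
#' `cfg$ba1_min_af`; PM2 and BA1 are mutually exclusive by construction),
#' PM4 (in-frame indel), PS1 (exact genomic or protein match to a P/LP
#' variant in ClinVar or the review committee — the identical amino-acid
#' change) and PM5 (a different amino-acid change at the same codon of a
#' P/LP variant). All remaining criteria are manual-entry only.
#'
#' @inheritParams assign_germline_medal
#' @return Tag data frame (origin `"auto"`).
#' @export
auto_tags <- function(variant, ann, pf, kb, gene_meta,
                      cfg = triage_config()) {
  tags <- .empty_tags()
  push <- function(code, note, pubmed = character(0)) {
    t <- acmg_tag(code, origin = "auto", pubmed_ids = pubmed, note = note)
    rbind(tags, t)
  }
  lof <- !is.null(gene_meta) && nrow(gene_meta) > 0L &&
    isTRUE(gene_meta$is_lof_gene[1L])
  if (.is_truncating(ann$consequence, cfg) && lof) {
    tags <- push("PVS1", sprintf("%s in loss-of-function gene %s",
                                 ann$consequence, ann$gene))
  }
  hs <- is_hotspot(kb, ann$gene, ann$codon, cfg)
  if (hs$is_hotspot && hs$cosmic) {
    tags <- push("PM1", sprintf("COSMIC hotspot at %s codon %d",
                                ann$gene, ann$codon))
  }
  exac <- unname(pf[["exac_nontcga"]])
  if (is.na(exac) || exac <= cfg$pm2_max_af) {
    tags <- push("PM2", if (is.na(exac)) {
      "absent from ExAC non-TCGA"
    } else {
      sprintf("ExAC non-TCGA frequency %g <= %g", exac, cfg$pm2_max_af)
    })
  } else if (exac > cfg$ba1_min_af) {
    tags <- push("BA1", sprintf("ExAC non-TCGA frequency %g > %g",
                                exac, cfg$ba1_min_af))
  }
  if (ann$consequence == "inframe_indel") {
    tags <- push("PM4", "in-frame protein insertion/deletion")
  }
  matches <- match_variant(kb, variant, gene = ann$gene, codon = ann$codon,
                           aa_ref = ann$p_aa_ref, aa_alt = ann$p_aa_alt)
  if (nrow(matches)) {
    plp <- matches$source %in% c("CLINVAR", "COMMITTEE") &
      !is.na(matches$call) & matches$call %in% c("P", "LP")
    exact <- plp & matches$grade %in% c("EXACT_GENOMIC", "EXACT_PROTEIN")
    codon_only <- plp & matches$grade == "SAME_CODON_DIFF_AA"
    if (any(exact)) {
      m <- matches[exact, ][1L, ]
      pm <- if (is.na(m$pubmed_ids)) character(0) else m$pubmed_ids
      tags <- push("PS1", sprintf("same amino-acid change as %s P/LP record",
                                  m$source), pm)
    }
    if (any(codon_only)) {
      m <- matches[codon_only, ][1L, ]
      pm <- if (is.na(m$pubmed_ids)) character(0) else m$pubmed_ids
      tags <- push("PM5", sprintf("different change at same codon as %s P/LP record",
                                  m$source), pm)
    }
  }
  tags
}

#' Construct an ACMG assessment from a tag set
#'
#' The classification is a pure function of the tag codes and is recomputed
#' on every edit.
#'
#' @param tags Tag data frame (see [acmg_tag()]).
#' @return Object of class `acmg_assessment`: list with `tags` and
#'   `classification`.
#' @export
acmg_assessment <- function(tags = .empty_tags()) {
  if (anyDuplicated(tags$code)) stop("a tag set contains each code at most once")
  structure(list(tags = tags, classification = classify_acmg(tags$code)),
            class = "acmg_assessment")
}

#' Add or remove ACMG evidence tags
#'
#' Automatically assigned tags may be removed by the analyst; manual tags
#' carry their provenance and PubMed IDs. Removing an absent code is a
#' warning no-op; adding a code already present replaces it. The five-tier
#' classification is recomputed.
#'
#' @param assessment An `acmg_assessment`.
#' @param add Tag data frame to add (see [acmg_tag()]), or `NULL`.
#' @param remove Character vector of codes to remove, or `NULL`.
#' @return The updated `acmg_assessment`.
#' @export
edit_tags <- function(assessment, add = NULL, remove = NULL) {
  stopifnot(inherits(assessment, "acmg_assessment"))
  tags <- assessment$tags
  if (!is.null(remove)) {
    absent <- setdiff(remove, tags$code)
    if (length(absent)) {
      warning(sprintf("code(s) not present, nothing removed: %s",
                      paste(absent, collapse = ", ")))
    }
    tags <- tags[!tags$code %in% remove, , drop = FALSE]
  }
  if (!is.null(add) && nrow(add)) {
    tags <- tags[!tags$code %in% add$code, , drop = FALSE]
    tags <- rbind(tags, add)
  }
  rownames(tags) <- NULL
  acmg_assessment(tags)
}

#' Serialize / deserialize an ACMG assessment as JSON
#'
#' @param assessment An `acmg_assessment`.
#' @param variant_key The variant's report key.
#' @return `acmg_to_json()`: a JSON string; `acmg_from_json()`: the
#'   round-tripped `acmg_assessment` (classification recomputed from the
#'   tag codes).
#' @export
acmg_to_json <- function(assessment, variant_key) {
  stopifnot(inherits(assessment, "acmg_assessment"))
  tags <- lapply(seq_len(nrow(assessment$tags)), function(i) {
    t <- assessment$tags[i, ]
    list(code = t$code, origin = t$origin,
         pubmed_ids = if (nzchar(t$pubmed_ids)) {
           strsplit(t$pubmed_ids, ",", fixed = TRUE)[[1L]]
         } else character(0),
         note = t$note)
  })
  jsonlite::toJSON(list(variant_key = variant_key, tags = tags,
                        classification = assessment$classification),
                   auto_unbox = TRUE)
}

#' @rdname acmg_to_json
#' @param json A JSON string produced by [acmg_to_json()].
#' @export
acmg_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  tags <- .empty_tags()
  for (t in x$tags) {
    tags <- rbind(tags, acmg_tag(t$code, origin = t$origin,
                                 pubmed_ids = unlist(t$pubmed_ids),
                                 note = t$note))
  }
  acmg_assessment(tags)
}

#' @export
print.acmg_assessment <- function(x, ...) {
  cat(sprintf("ACMG classification: %s\n", x$classification))
  if (nrow(x$tags)) {
    for (i in seq_len(nrow(x$tags))) {
      t <- x$tags[i, ]
      cat(sprintf("  %s (%s, %s)%s\n", t$code, t$strength, t$origin,
                  if (nzchar(t$note)) paste0(": ", t$note) else ""))
    }
  }
  invisible(x)
}
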