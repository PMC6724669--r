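CONSEQUENCES <- c("silent", "missense", "nonsense", "frameshift", "splice",
                  "splice_region", "inframe_indel", "stoploss", "utr",
                  "intron", "intergenic", "other")
TRUNCATING <- c("nonsense", "frameshift", "splice")
RETAINED_CONSEQUENCES <- c("silent", "missense", "nonsense", "frameshift",
                           "splice", "splice_region", "inframe_indel",
                           "stoploss")
# most severe first; ties broken by lexicographic transcript accession
SEVERITY_ORDER <- c("frameshift", "nonsense", "stoploss", "splice",
                    "splice_region", "inframe_indel", "missense", "silent",
                    "utr", "intron", "intergenic", "other")

# VEP-dialect consequence terms -> internal vocabulary
CONSEQUENCE_MAP <- c(
  silent = "silent", synonymous_variant = "silent",
  missense = "missense", missense_variant = "missense",
  nonsense = "nonsense", stop_gained = "nonsense",
  frameshift = "frameshift", frameshift_variant = "frameshift",
  splice = "splice", splice_donor_variant = "splice",
  splice_acceptor_variant = "splice",
  splice_region = "splice_region", splice_region_variant = "splice_region",
  inframe_indel = "inframe_indel", inframe_insertion = "inframe_indel",
  inframe_deletion = "inframe_indel",
  stoploss = "stoploss", stop_lost = "stoploss",
  utr = "utr", `5_prime_UTR_variant` = "utr", `3_prime_UTR_variant` = "utr",
  intron = "intron", intron_variant = "intron",
  intergenic = "intergenic", intergenic_variant = "intergenic")

.normalize_consequence <- function(x) {
  out <- unname(CONSEQUENCE_MAP[x])
  out[is.na(out)] <- "other"
  out
}

#' Load a per-variant transcript annotation table
#'
#' Consumes the tab-delimited annotation dialect (columns `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `transcript`, `consequence`, `cdna_hgvs`,
#' `protein_hgvs`). Consequence terms in the VEP dialect (`stop_gained`,
#' `synonymous_variant`, ...) are normalized to the internal vocabulary;
#' protein notations run through [parse_protein_change()] and rows with
#' unparseable protein fields are kept with `p_status = "failed"`.
#' Annotations whose variant key is not in `known_keys` are retained with a
#' warning count (annotation tables may be supersets of the VCF).
#'
#' @param path Path to the annotation table.
#' @param known_keys Optional character vector of variant keys from the VCF.
#' @return Data frame of annotations, ordered by key then transcript
#'   accession, with attribute `n_unknown_key`.
#' @export
load_annotations <- function(path, known_keys = NULL) {
  an <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", na.strings = c("NA", ""),
                          colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "gene", "transcript", "consequence",
            "cdna_hgvs", "protein_hgvs")
  miss <- setdiff(need, names(an))
  if (length(miss)) stop(sprintf("annotation table missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  v <- genomic_variant(canonical_chrom(an$chrom), as.integer(an$pos),
                       an$ref, an$alt)
  v <- normalize_variant(v)
  an$chrom <- v$chrom; an$pos <- v$pos; an$ref <- v$ref; an$alt <- v$alt
  an$key <- v$key
  an$consequence <- .normalize_consequence(an$consequence)
  an$original_consequence <- NA_character_
  pp <- parse_protein_change(ifelse(is.na(an$protein_hgvs), "", an$protein_hgvs))
  an$p_aa_ref <- pp$aa_ref; an$codon <- pp$codon
  an$p_aa_alt <- pp$aa_alt; an$p_status <- pp$status
  an$exon_boundary_dist <- NA_integer_
  an <- an[order(an$key, an$transcript), , drop = FALSE]
  rownames(an) <- NULL
  n_unknown <- if (is.null(known_keys)) 0L else sum(!an$key %in% known_keys)
  if (n_unknown > 0L) {
    warning(sprintf("%d annotation row(s) reference variants absent from the VCF set (retained)",
                    n_unknown))
  }
  attr(an, "n_unknown_key") <- n_unknown
  an
}

#' Load transcript exon models
#'
#' Tab-delimited columns `transcript`, `strand`, `exon_start`, `exon_end`
#' (1-based inclusive genomic intervals).
#'
#' @param path Path to the exon model file.
#' @return Data frame of exons.
#' @export
load_exons <- function(path) {
  ex <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", colClasses = "character")
  need <- c("transcript", "strand", "exon_start", "exon_end")
  miss <- setdiff(need, names(ex))
  if (length(miss)) stop(sprintf("exon model missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  ex$exon_start <- as.integer(ex$exon_start)
  ex$exon_end <- as.integer(ex$exon_end)
  if (any(!ex$strand %in% c("+", "-"))) stop("exon strand must be '+' or '-'")
  if (any(ex$exon_end < ex$exon_start)) stop("exon_end must be >= exon_start")
  ex
}

#' Promote silent/missense variants at exon boundaries to splice_region
#'
#' Silent and missense calls whose position lies within the configured
#' number of exonic bases of an exon edge (`cfg$splice_window_donor` at the
#' donor/3' edge, `cfg$splice_window_acceptor` at the acceptor/5' edge,
#' strand-aware) are reclassified as `splice_region` because they may
#' impact splicing; the original class is preserved in
#' `original_consequence` for the audit trail. Other consequence classes
#' are never altered and no annotation is ever demoted. Annotations whose
#' transcript has no exon model are left unchanged and counted.
#'
#' @param anns Annotation data frame from [load_annotations()].
#' @param exons Exon model data frame from [load_exons()].
#' @param cfg A [triage_config()].
#' @return `anns` with promotions applied, `exon_boundary_dist` filled in
#'   where computed, and attribute `n_no_exon_model`.
#' @export
reclassify_splice <- function(anns, exons, cfg = triage_config()) {
  n_skip <- 0L
  idx <- which(anns$consequence %in% c("silent", "missense"))
  for (i in idx) {
    tr <- anns$transcript[i]
    ex <- exons[exons$transcript == tr, , drop = FALSE]
    if (!nrow(ex)) { n_skip <- n_skip + 1L; next }
    pos <- anns$pos[i]
    inside <- ex$exon_start <= pos & pos <= ex$exon_end
    if (!any(inside)) next
    e <- ex[which(inside)[1L], ]
    if (e$strand == "+") {
      d_acc <- pos - e$exon_start + 1L   # exonic bases from acceptor edge
      d_don <- e$exon_end - pos + 1L     # exonic bases from donor edge
    } else {
      d_acc <- e$exon_end - pos + 1L
      d_don <- pos - e$exon_start + 1L
    }
    anns$exon_boundary_dist[i] <- min(d_acc, d_don)
    if (d_don <= cfg$splice_window_donor || d_acc <= cfg$splice_window_acceptor) {
      anns$original_consequence[i] <- anns$consequence[i]
      anns$consequence[i] <- "splice_region"
    }
  }
  attr(anns, "n_no_exon_model") <- n_skip
  anns
}

#' Retain only coding and splice-related annotations
#'
#' Keeps `silent`, `missense`, `nonsense`, `frameshift`, `splice`,
#' `splice_region`, `inframe_indel` and `stoploss` annotations (silent
#' variants are kept because in rare cases they cause aberrant splicing);
#' drops `utr`, `intron`, `intergenic` and `other`. A variant survives the
#' filter if any of its annotations does. Idempotent and monotone.
#'
#' @param anns Annotation data frame.
#' @return The retained annotation rows.
#' @export
filter_functional <- function(anns) {
  out <- anns[anns$consequence %in% RETAINED_CONSEQUENCES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the most severe annotation per variant and gene
#'
#' Severity order: frameshift > nonsense > stoploss > splice >
#' splice_region > inframe_indel > missense > silent > utr > intron >
#' intergenic > other. Ties are broken by lexicographic transcript
#' accession, so selection is deterministic.
#'
#' @param anns Annotation data frame.
#' @return One row per (key, gene), the selected annotation.
#' @export
select_most_severe <- function(anns) {
  if (nrow(anns) == 0L) return(anns)
  sev <- match(anns$consequence, SEVERITY_ORDER)
  ord <- order(anns$key, anns$gene, sev, anns$transcript)
  anns <- anns[ord, , drop = FALSE]
  keep <- !duplicated(paste(anns$key, anns$gene, sep = "\r"))
  out <- anns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
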