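#' Read a VCF file into a normalized variant table
#'
#' Streams variants out of a VCF v4.x file (plain or bgzip), decomposing
#' multi-allelic records into one variant per ALT allele and anchor-trimming
#' each allele pair. Symbolic ALT alleles (`<DEL>`, breakends, `*`) are
#' skipped and counted, as are alleles containing non-ACGT characters.
#' Record order is preserved. If a genotype column is present, the first
#' sample's GT string is carried through opaquely for reporting.
#'
#' @param path Path to the VCF file.
#' @param build Reference build label, `"GRCh37"` (default) or `"GRCh38"`
#'   (pass-through with a warning; no liftover).
#' @return A variant data frame (see [genomic_variant()]) with attributes
#'   `n_records`, `n_alleles`, `n_skipped_symbolic`, `n_skipped_invalid`.
#'   An empty VCF body yields a zero-row table, not an error.
#' @export
read_vcf <- function(path, build = "GRCh37") {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path))
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  gt <- if (ncol(vcf@gt) >= 2L) vcf@gt else NULL
  empty <- genomic_variant(character(0), integer(0), character(0),
                           character(0), build = "GRCh37")
  n_rec <- if (is.null(fix)) 0L else nrow(fix)
  chroms <- character(0); poss <- integer(0); refs <- character(0)
  alts <- character(0); gts <- character(0)
  n_alleles <- 0L; n_sym <- 0L; n_inv <- 0L
  for (r in seq_len(n_rec)) {
    ref <- toupper(fix[r, "REF"])
    rec_alts <- toupper(strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]])
    n_alleles <- n_alleles + length(rec_alts)
    gt_r <- if (!is.null(gt)) sub(":.*$", "", gt[r, 2L]) else NA_character_
    for (a in rec_alts) {
      symbolic <- grepl("<", a, fixed = TRUE) || grepl("[", a, fixed = TRUE) ||
        grepl("]", a, fixed = TRUE) || grepl(">", a, fixed = TRUE) ||
        a %in% c("*", ".")
      if (symbolic) {
        n_sym <- n_sym + 1L
        next
      }
      if (!grepl("^[ACGT]+$", a) || !grepl("^[ACGT]+$", ref)) {
        n_inv <- n_inv + 1L
        next
      }
      chroms <- c(chroms, fix[r, "CHROM"])
      poss <- c(poss, as.integer(fix[r, "POS"]))
      refs <- c(refs, ref)
      alts <- c(alts, a)
      gts <- c(gts, gt_r)
    }
  }
  out <- if (length(chroms)) {
    suppressWarnings(genomic_variant(chroms, poss, refs, alts, build = build,
                                     genotype = gts))
  } else empty
  out <- normalize_variant(out)
  attr(out, "n_records") <- n_rec
  attr(out, "n_alleles") <- n_alleles
  attr(out, "n_skipped_symbolic") <- n_sym
  attr(out, "n_skipped_invalid") <- n_inv
  out
}

#' Read a BED-like gene panel definition
#'
#' Tab-delimited columns `chrom`, `start`, `end`, `gene_symbol`; intervals
#' are half-open, 0-based (BED convention); `#` comment lines are allowed;
#' a header line beginning with `chrom` is tolerated.
#'
#' @param path Path to the panel file.
#' @param name Panel name (defaults to the file name).
#' @return An object of class `gene_panel`: a list with `name`,
#'   `intervals` (data frame) and `genes` (character vector).
#' @export
read_panel <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) && grepl("^chrom\\b", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) stop(sprintf("panel file is empty: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 4L)) {
    stop(sprintf("panel file needs 4 tab-delimited columns: %s", path))
  }
  intervals <- data.frame(
    chrom = canonical_chrom(vapply(parts, `[[`, "", 1L)),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    gene = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  if (any(is.na(intervals$start)) || any(is.na(intervals$end)) ||
      any(intervals$end <= intervals$start)) {
    stop(sprintf("panel intervals must satisfy 0 <= start < end: %s", path))
  }
  structure(list(name = if (is.null(name)) basename(path) else name,
                 intervals = intervals,
                 genes = sort(unique(intervals$gene))),
            class = "gene_panel")
}

#' Filter variants to a disease-gene panel
#'
#' A variant is retained iff its full REF span (1-based `[pos, pos +
#' nchar(ref) - 1]`, so deletions crossing a panel boundary are kept)
#' intersects any panel interval (half-open, 0-based). A variant inside two
#' genes' intervals is emitted once per gene.
#'
#' @param variants Variant data frame.
#' @param panel A `gene_panel` from [read_panel()].
#' @return The retained variants with an added `gene` column, one row per
#'   (variant, gene) pair, input order preserved.
#' @export
filter_to_panel <- function(variants, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  if (nrow(variants) == 0L) {
    out <- variants
    out$gene <- character(0)
    return(out)
  }
  vr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L))
  pr <- GenomicRanges::GRanges(
    panel$intervals$chrom,
    IRanges::IRanges(panel$intervals$start + 1L, panel$intervals$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, pr))
  qi <- S4Vectors::queryHits(hits)
  gene <- panel$intervals$gene[S4Vectors::subjectHits(hits)]
  keep <- !duplicated(paste(qi, gene))
  qi <- qi[keep]; gene <- gene[keep]
  ord <- order(qi)
  out <- variants[qi[ord], , drop = FALSE]
  out$gene <- gene[ord]
  rownames(out) <- NULL
  out
}

#' Read gene metadata (disease mechanism and inheritance)
#'
#' Tab-delimited columns `symbol`, `is_lof_gene` (0/1 or TRUE/FALSE),
#' `inheritance` (AD, AR, AD_AR, unknown), `panels` (comma-separated panel
#' names); `#` comments allowed.
#'
#' @param path Path to the gene metadata file.
#' @return Data frame keyed by `symbol` (one row per gene).
#' @export
read_gene_meta <- function(path) {
  gm <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", colClasses = "character")
  need <- c("symbol", "is_lof_gene", "inheritance", "panels")
  miss <- setdiff(need, names(gm))
  if (length(miss)) stop(sprintf("gene metadata missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(gm$symbol)) {
    stop("gene metadata must have exactly one record per gene symbol")
  }
  gm$is_lof_gene <- tolower(as.character(gm$is_lof_gene)) %in% c("1", "true", "t", "yes")
  bad <- !gm$inheritance %in% c("AD", "AR", "AD_AR", "unknown")
  if (any(bad)) stop(sprintf("unknown inheritance value: %s",
                             gm$inheritance[bad][1L]))
  gm
}
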