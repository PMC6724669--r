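#' @importFrom stats setNames
NULL

VTYPES <- c("SNV", "INS", "DEL", "MNV", "COMPLEX")
BUILDS <- c("GRCh37", "GRCh38")
MEDALS <- c("GOLD", "SILVER", "BRONZE", "UNKNOWN")
GATE_STATUSES <- c("passed", "failed_frequency", "rescued_by_exception",
                   "whitelisted", "blacklisted")

.validate_alleles <- function(ref, alt) {
  bad_ref <- !grepl("^[ACGT]+$", ref)
  if (any(bad_ref)) {
    stop(sprintf("invalid 'ref' allele: %s (must be non-empty over A/C/G/T)",
                 ref[bad_ref][1L]))
  }
  bad_alt <- !grepl("^[ACGT]+$", alt)
  if (any(bad_alt)) {
    stop(sprintf("invalid 'alt' allele: %s (must be non-empty over A/C/G/T)",
                 alt[bad_alt][1L]))
  }
  same <- ref == alt
  if (any(same)) {
    stop(sprintf("'ref' and 'alt' must differ (got %s>%s)",
                 ref[same][1L], alt[same][1L]))
  }
  invisible(TRUE)
}

#' Canonicalize chromosome names
#'
#' Strips a leading `chr` prefix (any case) and upper-cases the sex and
#' mitochondrial chromosomes, mapping `M` to `MT`. VCFs and knowledgebase
#' snapshots differ in dialect; all internal keys use the canonical form.
#'
#' @param chrom Character vector of chromosome names.
#' @return Canonical chromosome names.
#' @examples
#' canonical_chrom(c("chr1", "chrX", "MT", "chrM"))
#' @export
canonical_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  up <- toupper(chrom)
  sexmt <- up %in% c("X", "Y", "MT")
  chrom[sexmt] <- up[sexmt]
  chrom[up == "M"] <- "MT"
  chrom
}

# numeric rank used for deterministic output ordering
.chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 23
  r[chrom == "Y"] <- 24
  r[chrom == "MT"] <- 25
  r[is.na(r)] <- 26
  r
}

#' Classify an allele substitution by type
#'
#' The variant type is a pure function of the two allele strings:
#' 1/1 is an SNV; 1/k sharing the leading anchor base is an insertion;
#' k/1 sharing the anchor is a deletion; k/k with k > 1 is an MNV;
#' anything else is a complex substitution.
#'
#' @param ref,alt Character vectors of reference/alternate alleles
#'   (non-empty, A/C/G/T only, `ref != alt`).
#' @return Character vector over `SNV`, `INS`, `DEL`, `MNV`, `COMPLEX`.
#' @examples
#' classify_variant_type("C", "T")     # SNV
#' classify_variant_type("A", "AGG")   # INS
#' classify_variant_type("ACT", "GG")  # COMPLEX
#' @export
classify_variant_type <- function(ref, alt) {
  ref <- as.character(ref); alt <- as.character(alt)
  .validate_alleles(ref, alt)
  lr <- nchar(ref); la <- nchar(alt)
  vt <- rep("COMPLEX", length(ref))
  vt[lr == 1L & la == 1L] <- "SNV"
  vt[lr == 1L & la > 1L & substr(alt, 1L, 1L) == ref] <- "INS"
  vt[la == 1L & lr > 1L & substr(ref, 1L, 1L) == alt] <- "DEL"
  vt[lr > 1L & lr == la] <- "MNV"
  vt
}

#' Construct a table of genomic variants
#'
#' The unit flowing through the pipeline is one normalized allele
#' substitution on a reference build, represented as one row of a plain
#' data frame. Chromosome names are canonicalized; GRCh38 input is accepted
#' only as a labeled pass-through (no liftover is performed) with a warning
#' that coordinates must already be GRCh37-equivalent.
#'
#' @param chrom Chromosome names (canonicalized internally).
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Allele strings over A/C/G/T.
#' @param build Reference build, `"GRCh37"` (default) or `"GRCh38"`.
#' @param genotype Optional opaque per-sample genotype strings, carried
#'   through for reporting only.
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`, `vtype`,
#'   `build`, `key`, `genotype`.
#' @examples
#' genomic_variant("chr12", 100, "C", "T")
#' @export
genomic_variant <- function(chrom, pos, ref, alt, build = "GRCh37",
                            genotype = NA_character_) {
  build <- match.arg(build, BUILDS)
  if (build == "GRCh38") {
    warning("GRCh38 accepted as labeled pass-through only: coordinates must ",
            "already be GRCh37-equivalent (no liftover is performed)")
  }
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) stop("'pos' must be an integer >= 1")
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  vtype <- classify_variant_type(ref, alt)
  chrom <- canonical_chrom(chrom)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vtype = vtype, build = rep_len(build, length(pos)),
             key = variant_key(chrom, pos, ref, alt),
             genotype = rep_len(as.character(genotype), length(pos)),
             stringsAsFactors = FALSE)
}

#' Serialize a variant to its report key
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @return `"chrom:pos:ref>alt"` keys used in all reports and list files.
#' @examples
#' variant_key("12", 11803211, "C", "T")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

#' Parse a `"chrom:pos:ref>alt"` key back into its components
#'
#' @param key Character vector of keys.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):([0-9]+):([ACGT]+)>([ACGT]+)$", key))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop(sprintf("malformed variant key: %s", key[bad][1L]))
  data.frame(chrom = vapply(m, `[[`, "", 2L),
             pos = as.integer(vapply(m, `[[`, "", 3L)),
             ref = vapply(m, `[[`, "", 4L),
             alt = vapply(m, `[[`, "", 5L),
             stringsAsFactors = FALSE)
}

.normalize_one <- function(pos, ref, alt) {
  # trim shared trailing bases, then shared leading bases (keeping one
  # anchor base so INS/DEL stay representable), advancing pos per leading trim
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variants by anchor trimming
#'
#' Trims shared leading/trailing bases (keeping one anchor base for
#' insertions and deletions) so that VCF-derived keys match knowledgebase
#' keys. Normalization is idempotent and never changes the genomic edit
#' implied by `(pos, ref, alt)`. No reference-FASTA-aware left alignment is
#' performed.
#'
#' @param variants A variant data frame as returned by [genomic_variant()].
#' @return The normalized variant data frame (`vtype` and `key` recomputed).
#' @examples
#' v <- genomic_variant("1", 100, "TAC", "TAG")
#' normalize_variant(v)[, c("pos", "ref", "alt")]   # 102, C, G
#' @export
normalize_variant <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  .validate_alleles(variants$ref, variants$alt)
  for (i in seq_len(nrow(variants))) {
    n <- .normalize_one(variants$pos[i], variants$ref[i], variants$alt[i])
    variants$pos[i] <- n$pos
    variants$ref[i] <- n$ref
    variants$alt[i] <- n$alt
  }
  variants$vtype <- classify_variant_type(variants$ref, variants$alt)
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants
}
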