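#' Read a whitelist/blacklist variant-key file
#'
#' One `"chrom:pos:ref>alt"` key per line; `#` comments and blank lines
#' allowed.
#'
#' @param path Path to the list file, or `NULL`.
#' @return Character vector of keys (empty if `path` is `NULL`).
#' @export
read_variant_list <- function(path) {
  if (is.null(path)) return(character(0))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Run the full triage pipeline
#'
#' VCF in, classified result table out: reads and decomposes the VCF,
#' filters to the gene panel, applies splice-aware consequence adjustment
#' and the coding/splice retention filter, selects the most severe
#' annotation per variant and gene, looks up population frequencies and
#' predictions, assigns germline and somatic medals, generates the
#' automatic ACMG tags and the five-tier classification, and reports a
#' processing funnel (input records, alleles, panel-filtered,
#' functional-filtered, gate-passed, medaled).
#'
#' @param vcf Path to the input VCF.
#' @param panel Path to the gene-panel file (see [read_panel()]).
#' @param annotations Path to the annotation table (see [load_annotations()]).
#' @param exons Path to the exon model file (see [load_exons()]).
#' @param kb_dir Knowledgebase snapshot directory (see [load_snapshot()]).
#' @param gene_meta Path to the gene metadata file (see [read_gene_meta()]).
#' @param cfg A [triage_config()].
#' @param whitelist,blacklist Optional paths to variant-key list files.
#' @param build Reference build label for the VCF.
#' @return Object of class `triage_result`: list with `results` (one row
#'   per retained variant and gene, ordered by chromosome, position,
#'   alleles, gene), `funnel`, `config`, `kb_label`.
#' @export
run_pipeline <- function(vcf, panel, annotations, exons, kb_dir, gene_meta,
                         cfg = triage_config(), whitelist = NULL,
                         blacklist = NULL, build = "GRCh37") {
  for (p in c(vcf, panel, annotations, exons, gene_meta)) {
    if (!file.exists(p)) stop(sprintf("required input not found: %s", p))
  }
  variants <- read_vcf(vcf, build = build)
  pan <- read_panel(panel)
  gm <- read_gene_meta(gene_meta)
  kb <- load_snapshot(kb_dir)
  exon_models <- load_exons(exons)
  anns <- load_annotations(annotations)
  wl <- read_variant_list(whitelist)
  bl <- read_variant_list(blacklist)

  on_panel <- filter_to_panel(variants, pan)
  anns <- reclassify_splice(anns, exon_models, cfg)
  anns_kept <- filter_functional(anns)
  selected <- select_most_severe(anns_kept)

  # join: one candidate row per (variant, gene) pair with a retained
  # annotation for that gene
  sel_idx <- match(paste(on_panel$key, on_panel$gene, sep = "\r"),
                   paste(selected$key, selected$gene, sep = "\r"))
  keep <- !is.na(sel_idx)
  pairs <- on_panel[keep, , drop = FALSE]
  pair_ann <- selected[sel_idx[keep], , drop = FALSE]

  n <- nrow(pairs)
  rows <- vector("list", n)
  n_gate_passed <- 0L
  n_medaled <- 0L
  for (i in seq_len(n)) {
    v <- pairs[i, ]
    ann <- pair_ann[i, ]
    pf <- kb_frequencies(kb, v$key)
    pred <- kb_predictions(kb, v$key)
    gmeta <- gm[gm$symbol == ann$gene, , drop = FALSE]
    germ <- assign_germline_medal(v, ann, pf, pred, kb, gmeta, cfg,
                                  whitelist = wl, blacklist = bl)
    som <- assign_somatic_medal(v, ann, pred, kb, gmeta, cfg)
    tags <- auto_tags(v, ann, pf, kb, gmeta, cfg)
    assessment <- acmg_assessment(tags)
    if (germ$gate_status %in% c("passed", "rescued_by_exception", "whitelisted")) {
      n_gate_passed <- n_gate_passed + 1L
    }
    if (germ$medal != "UNKNOWN") n_medaled <- n_medaled + 1L
    rows[[i]] <- data.frame(
      variant_key = v$key, chrom = v$chrom, pos = v$pos, ref = v$ref,
      alt = v$alt, vtype = v$vtype, gene = ann$gene,
      transcript = ann$transcript, consequence = ann$consequence,
      original_consequence = ann$original_consequence,
      protein_change = render_protein_change(ann$p_aa_ref, ann$codon,
                                             ann$p_aa_alt),
      exac_nontcga = pf[["exac_nontcga"]], esp = pf[["esp"]],
      kg1000 = pf[["kg1000"]], pcgp = pf[["pcgp"]],
      prediction = aggregate_prediction(pred, cfg),
      germline_medal = germ$medal,
      germline_reasons = paste(sprintf("%s[%s]", germ$reasons$rule_id,
                                       germ$reasons$evidence),
                               collapse = "; "),
      gate_status = germ$gate_status,
      somatic_medal = som$medal,
      acmg_tags = paste(tags$code, collapse = ","),
      classification = assessment$classification,
      kb_label = kb$label,
      genotype = v$genotype,
      stringsAsFactors = FALSE)
  }
  results <- if (n) do.call(rbind, rows) else .empty_results()
  ord <- order(.chrom_rank(results$chrom), results$pos, results$ref,
               results$alt, results$gene)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL

  funnel <- list(
    n_records = attr(variants, "n_records"),
    n_alleles = attr(variants, "n_alleles"),
    n_skipped_symbolic = attr(variants, "n_skipped_symbolic"),
    n_variants = nrow(variants),
    n_panel = nrow(on_panel),
    n_functional = n,
    n_gate_passed = n_gate_passed,
    n_medaled = n_medaled)
  structure(list(results = results, funnel = funnel, config = cfg,
                 kb_label = kb$label),
            class = "triage_result")
}

.empty_results <- function() {
  data.frame(variant_key = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             vtype = character(0), gene = character(0),
             transcript = character(0), consequence = character(0),
             original_consequence = character(0),
             protein_change = character(0), exac_nontcga = numeric(0),
             esp = numeric(0), kg1000 = numeric(0), pcgp = numeric(0),
             prediction = character(0), germline_medal = character(0),
             germline_reasons = character(0), gate_status = character(0),
             somatic_medal = character(0), acmg_tags = character(0),
             classification = character(0), kb_label = character(0),
             genotype = character(0), stringsAsFactors = FALSE)
}

#' @export
print.triage_result <- function(x, ...) {
  f <- x$funnel
  cat(sprintf("Triage result (knowledgebase '%s')\n", x$kb_label))
  cat(sprintf("  VCF records: %d  alleles: %d  (symbolic skipped: %d)\n",
              f$n_records, f$n_alleles, f$n_skipped_symbolic))
  cat(sprintf("  variants: %d -> on panel: %d -> coding/splice: %d -> gate passed: %d -> medaled: %d\n",
              f$n_variants, f$n_panel, f$n_functional, f$n_gate_passed,
              f$n_medaled))
  medals <- table(factor(x$results$germline_medal, levels = MEDALS))
  cat(sprintf("  germline medals: %s\n",
              paste(sprintf("%s=%d", names(medals), medals), collapse = " ")))
  invisible(x)
}

#' Write triage reports
#'
#' TSV with a fixed, documented column order, and/or JSON embedding the
#' ACMG assessment of each row plus the funnel; both round-trip loadable.
#'
#' @param x A `triage_result`.
#' @param prefix Output path prefix (`<prefix>.tsv`, `<prefix>.json`).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(x, prefix, formats = c("tsv", "json")) {
  stopifnot(inherits(x, "triage_result"))
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character(0)
  if ("tsv" %in% formats) {
    path <- paste0(prefix, ".tsv")
    utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    written <- c(written, path)
  }
  if ("json" %in% formats) {
    path <- paste0(prefix, ".json")
    rows <- lapply(seq_len(nrow(x$results)), function(i) {
      r <- x$results[i, ]
      tag_codes <- if (nzchar(r$acmg_tags)) {
        strsplit(r$acmg_tags, ",", fixed = TRUE)[[1L]]
      } else character(0)
      list(variant_key = r$variant_key, gene = r$gene,
           transcript = r$transcript, consequence = r$consequence,
           original_consequence = r$original_consequence,
           germline_medal = r$germline_medal, gate_status = r$gate_status,
           germline_reasons = r$germline_reasons,
           somatic_medal = r$somatic_medal,
           assessment = list(variant_key = r$variant_key,
                             tags = lapply(tag_codes, function(code) {
                               list(code = code, origin = "auto",
                                    pubmed_ids = character(0), note = "")
                             }),
                             classification = r$classification),
           kb_label = r$kb_label)
    })
    jsonlite::write_json(list(funnel = x$funnel, results = rows), path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null", null = "null")
    written <- c(written, path)
  }
  invisible(written)
}

#' Read back a TSV report
#'
#' @param path Path to a `.tsv` written by [write_reports()].
#' @return The result data frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), colClasses = "character")
}

#' Print the full audit for one variant in a result table
#'
#' @param x A `triage_result`.
#' @param key A `"chrom:pos:ref>alt"` key.
#' @return The matching result rows, invisibly.
#' @export
variant_audit <- function(x, key) {
  stopifnot(inherits(x, "triage_result"))
  rows <- x$results[x$results$variant_key == key, , drop = FALSE]
  if (!nrow(rows)) {
    cat(sprintf("variant %s not present in results\n", key))
    return(invisible(rows))
  }
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    cat(sprintf("%s (%s, %s)\n", r$variant_key, r$gene, r$transcript))
    cat(sprintf("  consequence: %s%s  protein: %s\n", r$consequence,
                if (!is.na(r$original_consequence)) {
                  sprintf(" (promoted from %s)", r$original_consequence)
                } else "",
                ifelse(is.na(r$protein_change), "-", r$protein_change)))
    cat(sprintf("  ExAC non-TCGA: %s  prediction: %s\n",
                ifelse(is.na(r$exac_nontcga), "absent", format(r$exac_nontcga)),
                r$prediction))
    cat(sprintf("  germline medal: %s (gate %s)\n    %s\n", r$germline_medal,
                r$gate_status, gsub("; ", "\n    ", r$germline_reasons)))
    cat(sprintf("  somatic medal: %s\n", r$somatic_medal))
    cat(sprintf("  ACMG: [%s] -> %s\n", r$acmg_tags, r$classification))
    cat(sprintf("  knowledgebase: %s\n", r$kb_label))
  }
  invisible(rows)
}
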