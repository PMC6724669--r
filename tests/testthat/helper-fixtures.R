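# Shared fixtures, all built in code. The synthetic suite and its pipeline
# run are memoised per test session since several files assert against them.

.fixture_env <- new.env()

get_suite <- function() {
  if (is.null(.fixture_env$suite_dir)) {
    d <- file.path(tempdir(), "varmedal-suite-fixture")
    unlink(d, recursive = TRUE)
    .fixture_env$suite_manifest <- generate_suite(42, d)
    .fixture_env$suite_dir <- d
  }
  list(dir = .fixture_env$suite_dir, manifest = .fixture_env$suite_manifest)
}

run_suite_pipeline <- function() {
  if (is.null(.fixture_env$suite_result)) {
    s <- get_suite()
    d <- s$dir
    .fixture_env$suite_result <- run_pipeline(
      vcf = file.path(d, "suite.vcf"),
      panel = file.path(d, "panel.tsv"),
      annotations = file.path(d, "annotations.tsv"),
      exons = file.path(d, "exons.tsv"),
      kb_dir = file.path(d, "kb"),
      gene_meta = file.path(d, "gene_meta.tsv"),
      whitelist = file.path(d, "whitelist.txt"),
      blacklist = file.path(d, "blacklist.txt"))
  }
  .fixture_env$suite_result
}

# minimal in-code knowledgebase builder
make_kb <- function(curated = NULL, hotspots = NULL, frequencies = NULL,
                    predictions = NULL, label = "test-kb") {
  d <- tempfile("kb")
  dir.create(d)
  if (!is.null(curated)) {
    write.table(curated, file.path(d, "curated.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  }
  if (!is.null(hotspots)) {
    write.table(hotspots, file.path(d, "hotspots.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  }
  if (!is.null(frequencies)) {
    write.table(frequencies, file.path(d, "frequencies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  }
  if (!is.null(predictions)) {
    write.table(predictions, file.path(d, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  }
  load_snapshot(d, label = label)
}

empty_kb <- function() {
  if (is.null(.fixture_env$empty_kb)) {
    d <- tempfile("emptykb")
    dir.create(d)
    .fixture_env$empty_kb <- load_snapshot(d, label = "empty")
  }
  .fixture_env$empty_kb
}

curated_row <- function(source = "CLINVAR", chrom = NA, pos = NA, ref = NA,
                        alt = NA, gene = "G1", protein_change = NA,
                        call = "Pathogenic", stars = NA, pubmed_ids = NA) {
  data.frame(source = source, chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = gene, protein_change = protein_change, call = call,
             stars = stars, pubmed_ids = pubmed_ids, stringsAsFactors = FALSE)
}

hotspot_row <- function(source = "COSMIC", gene = "G1", codon = 12L,
                        tumor_count = 100L, aa_changes = "", curated_flag = 0L) {
  data.frame(source = source, gene = gene, codon = codon,
             tumor_count = tumor_count, aa_changes = aa_changes,
             curated_flag = curated_flag, stringsAsFactors = FALSE)
}

make_var <- function(chrom = "1", pos = 1000L, ref = "G", alt = "A") {
  genomic_variant(chrom, pos, ref, alt)
}

make_ann <- function(gene = "G1", consequence = "missense", codon = 100L,
                     aa_ref = "G", aa_alt = "S", transcript = "TR_G1") {
  data.frame(gene = gene, transcript = transcript, consequence = consequence,
             codon = as.integer(codon), p_aa_ref = aa_ref, p_aa_alt = aa_alt,
             p_status = "full", stringsAsFactors = FALSE)
}

gene_meta_row <- function(symbol = "G1", lof = FALSE) {
  data.frame(symbol = symbol, is_lof_gene = lof, inheritance = "AD",
             panels = "cancer", stringsAsFactors = FALSE)
}

pf_of <- function(exac = NA_real_, esp = NA_real_) {
  c(exac_nontcga = exac, esp = esp, kg1000 = NA_real_, pcgp = NA_real_)
}

no_pred <- function() list(calls = character(0), revel = NA_real_)
pred_of <- function(calls = character(0), revel = NA_real_) {
  list(calls = calls, revel = revel)
}

write_mini_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               records), path)
  path
}
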