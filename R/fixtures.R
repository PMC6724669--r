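# Deterministic generator of synthetic VCFs, panels, exon models,
# annotation tables and knowledgebase snapshots exercising every medal and
# auto-tag rule path, together with a machine-readable manifest of ground
# truth. Expected results in the manifest come exclusively from the
# decision-table oracles in oracles.R, never from the engines under test.

DB_CODES <- c("none", "iarc_exact", "clinvar_hi_exact", "clinvar_lo_exact",
              "committee_exact", "alsod_exact", "brca_exact",
              "clinvar_hi_codon", "clinvar_hi_pos", "alsod_codon",
              "clinvar_unmapped_exact")
HOTSPOT_CODES <- c("none", "cosmic", "cosmic_low", "pcgp")
PRED_CODES <- c("none", "damaging", "tolerated", "revel_high", "revel_low", "mixed")

.sv <- function(id, chrom, pos, ref, alt, gene, lof = FALSE, panel = "cancer",
                consequence = "missense", codon = NA_integer_,
                aa_ref = NA_character_, aa_alt = NA_character_, pstyle = 1L,
                db = "none", hotspot = "none", hotspot_aas = "",
                pred = "none", exac = NA_real_, esp = NA_real_,
                wl = FALSE, bl = FALSE, strand = "+", inheritance = "AD",
                at_donor_edge = FALSE, vcf_pad = FALSE,
                vcf_group = NA_integer_, chr_prefix = FALSE,
                extra_intron_tx = FALSE, in_panel = TRUE) {
  stopifnot(db %in% DB_CODES, hotspot %in% HOTSPOT_CODES, pred %in% PRED_CODES)
  data.frame(id = id, chrom = as.character(chrom), pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene, lof = lof, panel = panel,
             consequence = consequence, codon = as.integer(codon),
             aa_ref = aa_ref, aa_alt = aa_alt, pstyle = as.integer(pstyle),
             db = db, hotspot = hotspot, hotspot_aas = hotspot_aas,
             pred = pred, exac = exac, esp = esp, wl = wl, bl = bl,
             strand = strand, inheritance = inheritance,
             at_donor_edge = at_donor_edge, vcf_pad = vcf_pad,
             vcf_group = vcf_group, chr_prefix = chr_prefix,
             extra_intron_tx = extra_intron_tx, in_panel = in_panel,
             stringsAsFactors = FALSE)
}

.diff_aa <- function(aa) {
  if (is.na(aa)) return("D")
  setdiff(c("D", "E", "K"), aa)[1L]
}

.diff_alt_base <- function(ref, alt) {
  setdiff(c("T", "C", "A", "G"), c(substr(ref, 1L, 1L), alt))[1L]
}

.protein_str <- function(pstyle, aa_ref, codon, aa_alt) {
  if (pstyle == 0L || is.na(codon)) return(NA_character_)
  if (pstyle == 4L) {
    ref3 <- if (is.na(aa_ref)) "Ala" else unname(AA_1TO3[aa_ref])
    return(paste0("p.", ref3, codon, "fs"))
  }
  if (is.na(aa_ref) || is.na(aa_alt)) return(NA_character_)
  one <- paste0(aa_ref, codon, aa_alt)
  alt3 <- if (aa_alt == "=") "=" else unname(AA_1TO3[aa_alt])
  three <- paste0(unname(AA_1TO3[aa_ref]), codon, alt3)
  switch(pstyle,
         paste0("p.", three),          # p.Arg359Ter
         one,                          # R359*
         paste0("p.(", three, ")"))    # p.(Gly12Ser)
}

.vep_term <- function(cons, i) {
  # alternate between internal and VEP-dialect spellings, deterministically
  pick <- function(a, b) if (i %% 2L == 0L) a else b
  switch(cons,
         silent = pick("synonymous_variant", "silent"),
         missense = pick("missense_variant", "missense"),
         nonsense = pick("stop_gained", "nonsense"),
         frameshift = pick("frameshift_variant", "frameshift"),
         splice = pick("splice_donor_variant", "splice_acceptor_variant"),
         splice_region = "splice_region_variant",
         inframe_indel = pick("inframe_deletion", "inframe_insertion"),
         stoploss = "stop_lost",
         utr = pick("5_prime_UTR_variant", "3_prime_UTR_variant"),
         intron = "intron_variant",
         intergenic = "intergenic_variant",
         "other_term")
}

# evidence feature flags per spec row; the oracles consume these
.spec_features <- function(spec, cfg) {
  f <- data.frame(id = spec$id, stringsAsFactors = FALSE)
  f$blacklisted <- spec$bl
  f$whitelisted <- spec$wl
  f$exac <- spec$exac
  f$rescue_available <- spec$db %in% c("iarc_exact", "clinvar_hi_exact")
  f$truncating <- spec$consequence %in% TRUNCATING
  f$lof <- spec$lof
  f$exact_gold_db <- spec$db %in% c("iarc_exact", "clinvar_hi_exact", "committee_exact")
  f$exact_silver_db <- spec$db %in% c("clinvar_lo_exact", "alsod_exact", "brca_exact")
  f$imperfect_gold_db <- spec$db %in% c("clinvar_hi_codon", "clinvar_hi_pos")
  f$imperfect_silver_db <- spec$db == "alsod_codon"
  f$hotspot <- spec$hotspot %in% c("cosmic", "pcgp")
  f$cosmic_hotspot <- spec$hotspot == "cosmic"
  f$inframe <- spec$consequence == "inframe_indel"
  f$pred <- ifelse(spec$pred %in% c("damaging", "revel_high"), "damaging",
                   ifelse(spec$pred == "tolerated", "tolerated", "unknown"))
  f$hotspot_aa_match <- vapply(seq_len(nrow(spec)), function(i) {
    if (!f$hotspot[i]) return(FALSE)
    aas <- strsplit(spec$hotspot_aas[i], ",", fixed = TRUE)[[1L]]
    aas <- trimws(aas[nzchar(aas)])
    length(aas) == 0L ||
      (!is.na(spec$aa_alt[i]) && spec$aa_alt[i] %in% aas)
  }, logical(1L))
  f$exact_plp_clinvar_committee <- spec$db %in%
    c("clinvar_hi_exact", "clinvar_lo_exact", "committee_exact")
  f$same_codon_plp <- spec$db == "clinvar_hi_codon"
  promoted <- spec$at_donor_edge & spec$consequence %in% c("silent", "missense")
  f$final_consequence <- ifelse(promoted, "splice_region", spec$consequence)
  f$original_consequence <- ifelse(promoted, spec$consequence, NA_character_)
  f$retained <- f$final_consequence %in% RETAINED_CONSEQUENCES
  f
}

# normalized report keys for spec rows (match what the pipeline emits)
.spec_keys <- function(spec) {
  normalize_variant(genomic_variant(spec$chrom, spec$pos, spec$ref,
                                    spec$alt))$key
}

# expected results per spec row, computed only by the oracles
.spec_expectations <- function(spec, cfg) {
  feats <- .spec_features(spec, cfg)
  out <- data.frame(id = spec$id, key = .spec_keys(spec),
                    gene = spec$gene, in_panel = spec$in_panel,
                    retained = feats$retained,
                    consequence = feats$final_consequence,
                    original_consequence = feats$original_consequence,
                    stringsAsFactors = FALSE)
  out$germline_medal <- NA_character_
  out$somatic_medal <- NA_character_
  out$gate_status <- NA_character_
  out$acmg_tags <- NA_character_
  out$classification <- NA_character_
  for (i in seq_len(nrow(spec))) {
    if (!out$in_panel[i] || !out$retained[i]) next
    fi <- as.list(feats[i, ])
    g <- oracle_germline_medal(fi, cfg)
    tags <- oracle_auto_tags(fi, cfg)
    out$germline_medal[i] <- g$medal
    out$gate_status[i] <- g$gate_status
    out$somatic_medal[i] <- oracle_somatic_medal(fi, cfg)
    out$acmg_tags[i] <- paste(tags, collapse = ",")
    out$classification[i] <- oracle_classify(tags)
  }
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.curated_rows_for <- function(r) {
  empty <- data.frame(source = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      gene = character(0), protein_change = character(0),
                      call = character(0), stars = integer(0),
                      pubmed_ids = character(0), stringsAsFactors = FALSE)
  if (r$db == "none") return(empty)
  prot_same <- .protein_str(1L, r$aa_ref, r$codon, r$aa_alt)
  prot_diff <- if (!is.na(r$codon)) {
    da <- .diff_aa(r$aa_alt)
    ref3 <- if (is.na(r$aa_ref)) "Gly" else unname(AA_1TO3[r$aa_ref])
    paste0("p.", ref3, r$codon, unname(AA_1TO3[da]))
  } else NA_character_
  row <- function(source, genomic = TRUE, protein = NA_character_,
                  call = NA_character_, stars = NA_integer_,
                  alt = r$alt, pubmed = "100001") {
    data.frame(source = source,
               chrom = if (genomic) r$chrom else NA_character_,
               pos = if (genomic) r$pos else NA_integer_,
               ref = if (genomic) r$ref else NA_character_,
               alt = if (genomic) alt else NA_character_,
               gene = r$gene, protein_change = protein, call = call,
               stars = stars, pubmed_ids = pubmed, stringsAsFactors = FALSE)
  }
  switch(r$db,
    iarc_exact = row("IARC_TP53", protein = prot_same),
    clinvar_hi_exact = row("CLINVAR", protein = prot_same,
                           call = "Pathogenic", stars = 3L),
    clinvar_lo_exact = row("CLINVAR", protein = prot_same,
                           call = "Likely pathogenic", stars = 1L),
    committee_exact = row("COMMITTEE", protein = prot_same, call = "Pathogenic"),
    alsod_exact = row("ALSOD", genomic = FALSE, protein = prot_same,
                      call = "Pathogenic"),
    brca_exact = row("BRCA_SHARE", protein = prot_same, call = "Pathogenic"),
    clinvar_hi_codon = row("CLINVAR", genomic = FALSE, protein = prot_diff,
                           call = "Pathogenic", stars = 3L),
    clinvar_hi_pos = row("CLINVAR", alt = .diff_alt_base(r$ref, r$alt),
                         call = "Pathogenic", stars = 3L),
    alsod_codon = row("ALSOD", genomic = FALSE, protein = prot_diff,
                      call = "Pathogenic"),
    clinvar_unmapped_exact = row("CLINVAR", protein = prot_same,
                                 call = "conflicting interpretations",
                                 stars = 1L),
    empty)
}

.hotspot_rows_for <- function(r, cfg) {
  empty <- data.frame(source = character(0), gene = character(0),
                      codon = integer(0), tumor_count = integer(0),
                      aa_changes = character(0), curated_flag = integer(0),
                      stringsAsFactors = FALSE)
  if (r$hotspot == "none" || is.na(r$codon)) return(empty)
  switch(r$hotspot,
    cosmic = data.frame(source = "COSMIC", gene = r$gene, codon = r$codon,
                        tumor_count = 4000L, aa_changes = r$hotspot_aas,
                        curated_flag = 0L, stringsAsFactors = FALSE),
    cosmic_low = data.frame(source = "COSMIC", gene = r$gene, codon = r$codon,
                            tumor_count = cfg$hotspot_min_tumors - 1L,
                            aa_changes = r$hotspot_aas, curated_flag = 0L,
                            stringsAsFactors = FALSE),
    pcgp = data.frame(source = "PCGP", gene = r$gene, codon = r$codon,
                      tumor_count = 3L, aa_changes = r$hotspot_aas,
                      curated_flag = 1L, stringsAsFactors = FALSE),
    empty)
}

.prediction_rows_for <- function(r) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      algorithm = character(0), call = character(0),
                      revel = numeric(0), stringsAsFactors = FALSE)
  if (r$pred == "none") return(empty)
  cat_row <- function(algorithm, call) {
    data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
               algorithm = algorithm, call = call, revel = NA_real_,
               stringsAsFactors = FALSE)
  }
  revel_row <- function(score) {
    data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
               algorithm = "REVEL", call = NA_character_, revel = score,
               stringsAsFactors = FALSE)
  }
  switch(r$pred,
    damaging = rbind(cat_row("SIFT", "damaging"),
                     cat_row("Polyphen2", "damaging")),
    tolerated = rbind(cat_row("SIFT", "tolerated"),
                      cat_row("Polyphen2", "tolerated")),
    revel_high = revel_row(0.9),
    revel_low = revel_row(0.2),
    mixed = rbind(cat_row("SIFT", "damaging"),
                  cat_row("Polyphen2", "tolerated")),
    empty)
}

.write_suite_vcf <- function(spec, path, symbolic_line = NULL) {
  ord <- order(.chrom_rank(spec$chrom), spec$pos, spec$alt)
  sp <- spec[ord, , drop = FALSE]
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", sep = "\t"))
  done_groups <- integer(0)
  body <- character(0)
  for (i in seq_len(nrow(sp))) {
    r <- sp[i, ]
    if (!is.na(r$vcf_group)) {
      if (r$vcf_group %in% done_groups) next
      grp <- sp[!is.na(sp$vcf_group) & sp$vcf_group == r$vcf_group, ]
      alt <- paste(grp$alt, collapse = ",")
      done_groups <- c(done_groups, r$vcf_group)
    } else {
      alt <- r$alt
    }
    ref <- r$ref
    if (isTRUE(r$vcf_pad)) {
      ref <- paste0(ref, "G")
      alt <- paste0(alt, "G")
    }
    chrom <- if (isTRUE(r$chr_prefix)) paste0("chr", r$chrom) else r$chrom
    body <- c(body, paste(chrom, r$pos, ".", ref, alt, "50", "PASS", ".",
                          "GT", "0/1", sep = "\t"))
  }
  if (!is.null(symbolic_line)) body <- c(body, symbolic_line)
  writeLines(c(lines, body), path)
}

.write_suite_files <- function(spec, out_dir, cfg, symbolic_line = NULL,
                               extra_annotation = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kb_dir <- file.path(out_dir, "kb")
  dir.create(kb_dir, showWarnings = FALSE)

  .write_suite_vcf(spec, file.path(out_dir, "suite.vcf"), symbolic_line)

  # panel: one interval per in-panel gene covering all its variants
  inp <- spec[spec$in_panel, , drop = FALSE]
  panel <- do.call(rbind, lapply(split(inp, inp$gene), function(g) {
    data.frame(chrom = g$chrom[1L], start = min(g$pos) - 501L,
               end = max(g$pos) + 500L, gene = g$gene[1L],
               stringsAsFactors = FALSE)
  }))
  panel <- panel[order(.chrom_rank(panel$chrom), panel$start), , drop = FALSE]
  writeLines(c("# synthetic disease-gene panel",
               paste(panel$chrom, panel$start, panel$end, panel$gene,
                     sep = "\t")),
             file.path(out_dir, "panel.tsv"))

  gm <- spec[!duplicated(spec$gene),
             c("gene", "lof", "inheritance", "panel"), drop = FALSE]
  gm <- data.frame(symbol = gm$gene, is_lof_gene = as.integer(gm$lof),
                   inheritance = gm$inheritance, panels = gm$panel,
                   stringsAsFactors = FALSE)
  gm <- gm[order(gm$symbol), , drop = FALSE]
  .write_tsv(gm, file.path(out_dir, "gene_meta.tsv"))

  # exon models: one transcript per gene; donor-edge rows end at the variant
  ex <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    if (r$at_donor_edge) {
      data.frame(transcript = paste0("TR_", r$gene), strand = r$strand,
                 exon_start = r$pos - 29L, exon_end = r$pos,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(transcript = paste0("TR_", r$gene), strand = r$strand,
                 exon_start = r$pos - 50L, exon_end = r$pos + 50L,
                 stringsAsFactors = FALSE)
    }
  }))
  ex <- ex[!duplicated(ex$transcript), , drop = FALSE]
  .write_tsv(ex, file.path(out_dir, "exons.tsv"))

  ann <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    main <- data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
                       gene = r$gene, transcript = paste0("TR_", r$gene),
                       consequence = .vep_term(r$consequence, i),
                       cdna_hgvs = sprintf("c.%d%s>%s", i * 3L, r$ref, r$alt),
                       protein_hgvs = .protein_str(r$pstyle, r$aa_ref,
                                                   r$codon, r$aa_alt),
                       stringsAsFactors = FALSE)
    if (isTRUE(r$extra_intron_tx)) {
      extra <- main
      extra$transcript <- paste0("TR_", r$gene, "_B")
      extra$consequence <- "intron_variant"
      extra$protein_hgvs <- NA_character_
      main <- rbind(main, extra)
    }
    main
  }))
  if (!is.null(extra_annotation)) ann <- rbind(ann, extra_annotation)
  .write_tsv(ann, file.path(out_dir, "annotations.tsv"))

  curated <- do.call(rbind, lapply(seq_len(nrow(spec)),
                                   function(i) .curated_rows_for(spec[i, ])))
  # distractor records that match nothing (benign, remote positions)
  curated <- rbind(curated, data.frame(
    source = c("CLINVAR", "CLINVAR"), chrom = c("2", "2"),
    pos = c(5000100L, 5000200L), ref = c("A", "C"), alt = c("G", "T"),
    gene = c("ZZDIST1", "ZZDIST2"), protein_change = NA_character_,
    call = c("Benign", "Likely benign"), stars = c(2L, 1L),
    pubmed_ids = NA_character_, stringsAsFactors = FALSE))
  .write_tsv(curated, file.path(kb_dir, "curated.tsv"))

  hotspots <- do.call(rbind, lapply(seq_len(nrow(spec)),
                                    function(i) .hotspot_rows_for(spec[i, ], cfg)))
  hotspots <- rbind(hotspots, data.frame(
    source = "COSMIC", gene = "ZZDIST1", codon = 999L, tumor_count = 500L,
    aa_changes = "W", curated_flag = 0L, stringsAsFactors = FALSE))
  .write_tsv(hotspots, file.path(kb_dir, "hotspots.tsv"))

  fr <- spec[!is.na(spec$exac) | !is.na(spec$esp), , drop = FALSE]
  freqs <- data.frame(chrom = fr$chrom, pos = fr$pos, ref = fr$ref,
                      alt = fr$alt, exac_nontcga = fr$exac, esp = fr$esp,
                      kg1000 = NA_real_, pcgp = NA_real_,
                      stringsAsFactors = FALSE)
  .write_tsv(freqs, file.path(kb_dir, "frequencies.tsv"))

  preds <- do.call(rbind, lapply(seq_len(nrow(spec)),
                                 function(i) .prediction_rows_for(spec[i, ])))
  .write_tsv(preds, file.path(kb_dir, "predictions.tsv"))

  keys <- .spec_keys(spec)
  writeLines(c("# always-medal custom variants", keys[spec$wl]),
             file.path(out_dir, "whitelist.txt"))
  writeLines(c("# never-medal custom variants", keys[spec$bl]),
             file.path(out_dir, "blacklist.txt"))
  invisible(out_dir)
}

.archetype_spec <- function() {
  rows <- list(
    # paper-anchored archetypes -------------------------------------------
    .sv("etv6_nonsense", "12", 2001000L, "C", "T", "ETV6", lof = TRUE,
        panel = "cancer,hematological", consequence = "nonsense",
        codon = 359L, aa_ref = "R", aa_alt = "*", pstyle = 1L),
    .sv("nras_hotspot", "1", 1150100L, "G", "A", "NRAS",
        consequence = "missense", codon = 12L, aa_ref = "G", aa_alt = "S",
        pstyle = 3L, db = "clinvar_hi_codon", hotspot = "cosmic",
        hotspot_aas = "S,D,V"),
    .sv("notch1_dual", "9", 1350100L, "G", "T", "NOTCH1",
        panel = "cardiovascular", consequence = "missense", codon = 1350L,
        aa_ref = "R", aa_alt = "L", pstyle = 2L, db = "clinvar_lo_exact",
        pred = "tolerated", esp = 2e-4, chr_prefix = TRUE),
    .sv("mlh1_silent_boundary", "3", 3700020L, "C", "T", "MLH1", lof = TRUE,
        consequence = "silent", codon = 294L, aa_ref = "L", aa_alt = "=",
        pstyle = 1L, at_donor_edge = TRUE, chr_prefix = TRUE),
    .sv("sod1_ala5val", "21", 800050L, "C", "T", "SOD1", panel = "als",
        consequence = "missense", codon = 5L, aa_ref = "A", aa_alt = "V",
        pstyle = 1L, db = "alsod_exact", pred = "damaging",
        inheritance = "AD"),
    # frequency-gate rescues ----------------------------------------------
    .sv("tp53_rescued_iarc1", "17", 757210L, "G", "A", "TP53", lof = TRUE,
        consequence = "missense", codon = 245L, aa_ref = "G", aa_alt = "S",
        db = "iarc_exact", exac = 0.002),
    .sv("tp53_rescued_iarc2", "17", 758300L, "C", "T", "TP53", lof = TRUE,
        consequence = "missense", codon = 175L, aa_ref = "R", aa_alt = "H",
        db = "iarc_exact", exac = 0.005, pred = "damaging"),
    .sv("rescued_clinvar", "17", 900100L, "G", "A", "BRCA1",
        consequence = "missense", codon = 1699L, aa_ref = "R", aa_alt = "Q",
        db = "clinvar_hi_exact", exac = 0.002),
    # whitelist / blacklist -----------------------------------------------
    .sv("wl_1", "5", 502000L, "G", "A", "WGENE1", codon = 101L,
        aa_ref = "G", aa_alt = "S", wl = TRUE),
    .sv("wl_2", "5", 504000L, "C", "T", "WGENE2", codon = 102L,
        aa_ref = "A", aa_alt = "V", wl = TRUE),
    .sv("wl_3", "5", 506000L, "G", "T", "WGENE3", codon = 103L,
        aa_ref = "R", aa_alt = "L", wl = TRUE),
    .sv("bl_1", "6", 602000L, "G", "A", "BGENE1", codon = 111L,
        aa_ref = "G", aa_alt = "S", bl = TRUE),
    .sv("bl_2", "6", 604000L, "C", "T", "BGENE2", lof = TRUE,
        consequence = "nonsense", codon = 112L, aa_ref = "R", aa_alt = "*",
        bl = TRUE),
    .sv("bl_3", "6", 606000L, "G", "T", "BGENE3", codon = 113L,
        aa_ref = "A", aa_alt = "D", pred = "damaging", bl = TRUE),
    # frequency-gate failures ---------------------------------------------
    .sv("freq_fail_1", "7", 702000L, "G", "A", "FGENE1", codon = 121L,
        aa_ref = "G", aa_alt = "S", pred = "damaging", exac = 0.002),
    .sv("freq_fail_2", "7", 704000L, "C", "T", "FGENE2", codon = 122L,
        aa_ref = "A", aa_alt = "V", pred = "damaging", exac = 0.01),
    .sv("freq_fail_3", "7", 706000L, "G", "T", "FGENE3", codon = 123L,
        aa_ref = "R", aa_alt = "L", pred = "damaging", exac = 0.0015),
    .sv("ba1_common", "7", 708000L, "A", "G", "BAGENE", codon = 124L,
        aa_ref = "T", aa_alt = "A", exac = 0.2),
    # silver / bronze coverage --------------------------------------------
    .sv("trunc_non_lof", "8", 802000L, "C", "CAT", "TNLG",
        consequence = "frameshift", codon = 210L, aa_ref = "A", pstyle = 4L),
    .sv("inframe_del", "8", 804000L, "CTTTG", "CG", "INFG",
        consequence = "inframe_indel", pstyle = 0L),
    .sv("tolerated_1", "10", 1002000L, "G", "A", "TOL1", codon = 131L,
        aa_ref = "G", aa_alt = "S", pred = "tolerated", exac = 0),
    .sv("tolerated_2", "10", 1004000L, "C", "T", "TOL2", codon = 132L,
        aa_ref = "A", aa_alt = "V", pred = "tolerated"),
    .sv("imperfect_silver", "10", 1006000L, "G", "A", "IMPS", codon = 55L,
        aa_ref = "G", aa_alt = "R", db = "alsod_codon"),
    .sv("no_evidence", "11", 1102000L, "G", "A", "NOEV", codon = 88L,
        aa_ref = "G", aa_alt = "S", db = "clinvar_unmapped_exact",
        exac = 5e-4),
    .sv("same_pos_diff_allele", "11", 1104000L, "G", "A", "SPOS",
        codon = 99L, aa_ref = "G", aa_alt = "S", db = "clinvar_hi_pos"),
    # functional-filter drops ---------------------------------------------
    .sv("utr_drop", "13", 1302000L, "G", "A", "UTRG", consequence = "utr",
        pstyle = 0L),
    .sv("intron_drop", "13", 1304000L, "C", "T", "INTG",
        consequence = "intron", pstyle = 0L),
    # multi-allelic record -------------------------------------------------
    .sv("multiallelic_a", "14", 1402000L, "A", "G", "MAG", codon = 120L,
        aa_ref = "L", aa_alt = "S", vcf_group = 1L),
    .sv("multiallelic_b", "14", 1402000L, "A", "T", "MAG", codon = 120L,
        aa_ref = "L", aa_alt = "C", vcf_group = 1L),
    # variant-type coverage ------------------------------------------------
    .sv("mnv_missense", "15", 1502000L, "AC", "GT", "MNVG", codon = 33L,
        aa_ref = "A", aa_alt = "V", pred = "damaging"),
    .sv("complex_frameshift", "15", 1504000L, "ACT", "GG", "CPXG",
        lof = TRUE, consequence = "frameshift", codon = 44L, aa_ref = "T",
        pstyle = 4L),
    .sv("splice_lof", "16", 1602000L, "G", "A", "SPLG", lof = TRUE,
        consequence = "splice", pstyle = 0L),
    .sv("padded_record", "16", 1604000L, "C", "T", "PADG", codon = 66L,
        aa_ref = "P", aa_alt = "L", pred = "tolerated", vcf_pad = TRUE),
    .sv("multi_transcript", "18", 1802000L, "G", "A", "MTXG", codon = 150L,
        aa_ref = "E", aa_alt = "K", pred = "mixed",
        extra_intron_tx = TRUE),
    # hotspot variants ------------------------------------------------------
    .sv("pcgp_hotspot", "19", 1902000L, "G", "A", "PCGPG", codon = 61L,
        aa_ref = "Q", aa_alt = "K", hotspot = "pcgp", hotspot_aas = ""),
    .sv("cosmic_below_threshold", "19", 1904000L, "C", "T", "CLOW",
        codon = 600L, aa_ref = "V", aa_alt = "M", hotspot = "cosmic_low",
        hotspot_aas = "M", pred = "revel_high"),
    # remaining database tiers ---------------------------------------------
    .sv("committee_match", "20", 2002000L, "G", "A", "COMG", codon = 30L,
        aa_ref = "G", aa_alt = "D", db = "committee_exact"),
    .sv("brca_share_match", "20", 2004000L, "C", "T", "BSHG", codon = 400L,
        aa_ref = "S", aa_alt = "F", db = "brca_exact"),
    # off-panel ------------------------------------------------------------
    .sv("off_panel_1", "22", 2202000L, "G", "A", "OFFP1", codon = 10L,
        aa_ref = "G", aa_alt = "S", in_panel = FALSE),
    .sv("off_panel_2", "22", 2204000L, "C", "T", "OFFP2", codon = 11L,
        aa_ref = "A", aa_alt = "V", in_panel = FALSE)
  )
  do.call(rbind, rows)
}

#' Generate the full synthetic fixture suite
#'
#' Emits a VCF with at least one variant per medal rule and per auto-tag
#' rule — including the five named archetypes (a nonsense truncation in a
#' loss-of-function leukemia gene, a hotspot missense with a same-codon
#' curated pathogenic record, a dual-medal missense matched in ClinVar but
#' predicted tolerated, a silent variant at an exon donor edge, and an
#' ALS-database missense) — together with the matching panel, gene
#' metadata, exon model, annotation table, knowledgebase snapshot,
#' whitelist and blacklist, plus a JSON manifest mapping each variant key
#' to its expected medals, gate status, auto tags and classification. All
#' expectations in the manifest are computed by the independent
#' decision-table oracles, never by the engines under test. Output is
#' byte-identical for a given seed.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [triage_config()] (defaults).
#' @return The manifest, invisibly.
#' @export
generate_suite <- function(seed, out_dir, cfg = triage_config()) {
  set.seed(seed)
  spec <- .archetype_spec()
  stopifnot(!anyDuplicated(spec$id))
  symbolic <- paste("14", 1402100L, ".", "A", "<DEL>", "50", "PASS",
                    "SVTYPE=DEL", "GT", "0/1", sep = "\t")
  extra_ann <- data.frame(chrom = "22", pos = 999999L, ref = "G", alt = "C",
                          gene = "EXTRAG", transcript = "TR_EXTRAG",
                          consequence = "missense_variant",
                          cdna_hgvs = "c.10G>C", protein_hgvs = "p.Gly4Ala",
                          stringsAsFactors = FALSE)
  .write_suite_files(spec, out_dir, cfg, symbolic_line = symbolic,
                     extra_annotation = extra_ann)
  exp <- .spec_expectations(spec, cfg)

  eval_rows <- exp[exp$in_panel & exp$retained, , drop = FALSE]
  medal_counts <- table(factor(eval_rows$germline_medal, levels = MEDALS))
  gate_counts <- table(factor(eval_rows$gate_status, levels = GATE_STATUSES))
  # generator self-check: every medal tier and every gate status covered
  stopifnot(all(medal_counts >= 3L),
            gate_counts[["whitelisted"]] >= 3L,
            gate_counts[["blacklisted"]] >= 3L,
            gate_counts[["failed_frequency"]] >= 3L,
            gate_counts[["rescued_by_exception"]] >= 3L,
            gate_counts[["passed"]] >= 3L)

  n_groups <- length(unique(spec$vcf_group[!is.na(spec$vcf_group)]))
  n_grouped <- sum(!is.na(spec$vcf_group))
  funnel <- list(
    n_records = nrow(spec) - n_grouped + n_groups + 1L,
    n_alleles = nrow(spec) + 1L,
    n_skipped_symbolic = 1L,
    n_variants = nrow(spec),
    n_panel = sum(exp$in_panel),
    n_functional = sum(exp$in_panel & exp$retained),
    n_gate_passed = sum(exp$in_panel & exp$retained &
                          exp$gate_status %in% c("passed",
                                                 "rescued_by_exception",
                                                 "whitelisted")),
    n_medaled = sum(exp$in_panel & exp$retained &
                      exp$germline_medal != "UNKNOWN"))

  variants <- lapply(seq_len(nrow(exp)), function(i) {
    e <- exp[i, ]
    list(id = e$id, gene = e$gene, in_panel = e$in_panel,
         retained = e$retained, consequence = e$consequence,
         original_consequence = e$original_consequence,
         germline_medal = e$germline_medal, somatic_medal = e$somatic_medal,
         gate_status = e$gate_status,
         acmg_tags = if (is.na(e$acmg_tags) || !nzchar(e$acmg_tags)) {
           character(0)
         } else strsplit(e$acmg_tags, ",", fixed = TRUE)[[1L]],
         classification = e$classification)
  })
  names(variants) <- exp$key
  manifest <- list(seed = seed, label = "suite-v1",
                   medal_counts = as.list(medal_counts),
                   gate_counts = as.list(gate_counts),
                   funnel = funnel, variants = variants)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(manifest)
}

#' Generate a randomized rule battery
#'
#' Samples `n` variants whose evidence features (consequence, gene
#' mechanism, database match kind, hotspot kind, prediction profile,
#' population frequency, white/blacklist membership) are drawn from fixed
#' choice sets spanning every medal rule, materializes them as a complete
#' input set, and returns the feature table plus oracle expectations.
#' Feature combinations that cannot be expressed in the file dialects
#' (protein-level database matches for consequences that carry no codon)
#' are excluded at sampling time.
#'
#' @param n Number of variants.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param cfg A [triage_config()].
#' @return List with `spec` (feature table) and `expected` (oracle
#'   expectations data frame).
#' @export
generate_rule_battery <- function(n = 500L, seed = 1L, out_dir,
                                  cfg = triage_config()) {
  set.seed(seed)
  genomic_dbs <- c("none", "iarc_exact", "clinvar_hi_exact",
                   "clinvar_lo_exact", "committee_exact", "brca_exact",
                   "clinvar_hi_pos", "clinvar_unmapped_exact")
  codon_dbs <- c(genomic_dbs, "clinvar_hi_codon", "alsod_codon")
  full_dbs <- c(codon_dbs, "alsod_exact")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cons <- sample(c("nonsense", "frameshift", "splice", "missense",
                     "silent", "inframe_indel"), 1L,
                   prob = c(0.15, 0.1, 0.1, 0.4, 0.15, 0.1))
    codon <- 10L + (i %% 400L)
    pos <- 100000L + i * 2000L
    aa_ref <- NA_character_; aa_alt <- NA_character_; pstyle <- 0L
    ref <- "G"; alt <- "A"
    if (cons == "missense") { aa_ref <- "G"; aa_alt <- "S"; pstyle <- 1L + i %% 3L }
    if (cons == "silent") { aa_ref <- "L"; aa_alt <- "="; pstyle <- 1L }
    if (cons == "nonsense") { aa_ref <- "R"; aa_alt <- "*"; pstyle <- 1L + i %% 2L }
    if (cons == "frameshift") { aa_ref <- "A"; pstyle <- 4L; ref <- "GA"; alt <- "G" }
    if (cons == "inframe_indel") { ref <- "GACA"; alt <- "G" }
    has_full_protein <- cons %in% c("missense", "silent", "nonsense")
    has_codon <- has_full_protein || cons == "frameshift"
    if (!has_codon) codon <- NA_integer_
    db <- if (has_full_protein) {
      sample(full_dbs, 1L)
    } else if (has_codon) {
      sample(codon_dbs, 1L)
    } else {
      sample(genomic_dbs, 1L)
    }
    hotspot <- if (has_codon) {
      sample(HOTSPOT_CODES, 1L, prob = c(0.55, 0.2, 0.1, 0.15))
    } else "none"
    hotspot_aas <- if (hotspot == "none") "" else if (is.na(aa_alt)) {
      sample(c("", "Q"), 1L)
    } else {
      sample(c(paste0(aa_alt, ",D"), "D,E", ""), 1L)
    }
    pred <- sample(PRED_CODES, 1L)
    exac <- sample(c(NA_real_, 0, 5e-5, 1e-3, 2e-3, 0.2), 1L,
                   prob = c(0.35, 0.1, 0.15, 0.15, 0.15, 0.1))
    wlbl <- sample(c("none", "wl", "bl"), 1L, prob = c(0.9, 0.05, 0.05))
    rows[[i]] <- .sv(sprintf("b%04d", i), "1", pos, ref, alt,
                     sprintf("BG%04d", i), lof = sample(c(TRUE, FALSE), 1L),
                     consequence = cons, codon = codon, aa_ref = aa_ref,
                     aa_alt = aa_alt, pstyle = pstyle, db = db,
                     hotspot = hotspot, hotspot_aas = hotspot_aas,
                     pred = pred, exac = exac, wl = wlbl == "wl",
                     bl = wlbl == "bl")
  }
  spec <- do.call(rbind, rows)
  .write_suite_files(spec, out_dir, cfg)
  list(spec = spec, expected = .spec_expectations(spec, cfg))
}

#' Generate a frequency-sweep fixture
#'
#' One frequency row per grid point for the same variant key, written as a
#' driver listing for threshold-recovery scans.
#'
#' @param variant_template List with `chrom`, `pos`, `ref`, `alt`.
#' @param grid Numeric vector of allele frequencies in `[0, 1]`.
#' @param out_dir Output directory.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `exac_nontcga` (one row per grid point), also written to
#'   `sweep.tsv` in `out_dir`.
#' @export
generate_frequency_sweep <- function(variant_template, grid, out_dir) {
  stopifnot(all(grid >= 0 & grid <= 1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(chrom = variant_template$chrom,
                   pos = as.integer(variant_template$pos),
                   ref = variant_template$ref, alt = variant_template$alt,
                   exac_nontcga = as.numeric(grid),
                   stringsAsFactors = FALSE)
  .write_tsv(df, file.path(out_dir, "sweep.tsv"))
  df
}
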