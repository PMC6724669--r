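test_that("five-tier classification worked examples", {
  expect_identical(classify_acmg(c("PVS1", "PM2")), "LP")
  expect_identical(classify_acmg(character(0)), "VUS")
  expect_identical(classify_acmg("BA1"), "B")
  expect_identical(classify_acmg(c("PS1", "PS3", "PM1", "PM2")), "P")
  expect_identical(classify_acmg(c("PVS1", "PS1")), "P")
  expect_identical(classify_acmg(c("PM1", "PM2", "PM5")), "LP")
  expect_identical(classify_acmg(c("BS1", "BS2")), "B")
  expect_identical(classify_acmg(c("BS1", "BP4")), "LB")
  expect_identical(classify_acmg(c("BP4", "BP7")), "LB")
  # conflicting evidence -> VUS
  expect_identical(classify_acmg(c("PVS1", "PS1", "BA1")), "VUS")
  expect_error(classify_acmg("PX9"), "unknown ACMG code")
})

test_that("classification agrees with the brute-force oracle on all subsets of <= 6 tags", {
  alphabet <- c("PVS1", "PS1", "PS3", "PM1", "PM2", "PM4", "PM5", "PP3",
                "BA1", "BS1", "BP4")
  n_checked <- 0L
  for (k in 0:6) {
    combos <- combn(alphabet, k, simplify = FALSE)
    for (codes in combos) {
      expect_identical(classify_acmg(codes), oracle_classify(codes),
                       info = paste(codes, collapse = "+"))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1486L)
})

test_that("classification is monotone on the pathogenic side, except via the conflict clause", {
  rank5 <- function(x) match(x, c("B", "LB", "VUS", "LP", "P"))
  base_sets <- list(character(0), "PM2", c("PVS1", "PM2"), c("PS1", "PM2"),
                    c("PM1", "PM2", "PM5"), "PS1")
  p_tags <- c("PVS1", "PS3", "PM6", "PP1")
  for (base in base_sets) {
    for (tag in setdiff(p_tags, base)) {
      before <- classify_acmg(base)
      after <- classify_acmg(c(base, tag))
      expect_gte(rank5(after), rank5(before),
                 label = paste(paste(base, collapse = "+"), "+", tag))
    }
  }
  # the conflict clause is the one sanctioned exception
  expect_identical(classify_acmg(c("BA1", "PVS1", "PS1")), "VUS")
  expect_identical(classify_acmg("BA1"), "B")
})

test_that("automated tags: truncating LoF, hotspot, frequency, indel, PS1/PM5 split", {
  cfg <- triage_config()
  gm_lof <- gene_meta_row("ETV6", lof = TRUE)
  v <- make_var(chrom = "12", pos = 2001000L, ref = "C", alt = "T")
  ann <- make_ann(gene = "ETV6", consequence = "nonsense", codon = 359L,
                  aa_ref = "R", aa_alt = "*")
  tags <- auto_tags(v, ann, pf_of(), empty_kb(), gm_lof, cfg)
  expect_setequal(tags$code, c("PVS1", "PM2"))
  expect_true(all(tags$origin == "auto"))

  # PS1: identical amino-acid change in a P/LP ClinVar record
  kb_ps1 <- make_kb(curated = curated_row(gene = "G1",
                                          protein_change = "p.Gly100Ser",
                                          call = "Pathogenic", stars = 2L))
  t1 <- auto_tags(make_var(), make_ann(), pf_of(), kb_ps1, gene_meta_row(), cfg)
  expect_true("PS1" %in% t1$code)
  expect_false("PM5" %in% t1$code)
  # PM5: different change at the same codon
  kb_pm5 <- make_kb(curated = curated_row(gene = "G1",
                                          protein_change = "p.Gly100Asp",
                                          call = "Pathogenic", stars = 2L))
  t2 <- auto_tags(make_var(), make_ann(), pf_of(), kb_pm5, gene_meta_row(), cfg)
  expect_true("PM5" %in% t2$code)
  expect_false("PS1" %in% t2$code)
  # non-ClinVar/committee sources yield neither
  kb_alsod <- make_kb(curated = curated_row(source = "ALSOD", gene = "G1",
                                            protein_change = "p.Gly100Ser",
                                            call = "Pathogenic"))
  t3 <- auto_tags(make_var(), make_ann(), pf_of(), kb_alsod, gene_meta_row(), cfg)
  expect_false(any(c("PS1", "PM5") %in% t3$code))

  # PM4 for in-frame indels
  t4 <- auto_tags(make_var(ref = "GAAA", alt = "G"),
                  make_ann(consequence = "inframe_indel", codon = NA,
                           aa_ref = NA, aa_alt = NA),
                  pf_of(), empty_kb(), gene_meta_row(), cfg)
  expect_true("PM4" %in% t4$code)

  # PM1 only from COSMIC hotspots
  kb_pcgp <- make_kb(hotspots = hotspot_row(source = "PCGP", gene = "G1",
                                            codon = 100L, tumor_count = 3L,
                                            curated_flag = 1L))
  t5 <- auto_tags(make_var(), make_ann(), pf_of(), kb_pcgp, gene_meta_row(), cfg)
  expect_false("PM1" %in% t5$code)
  kb_cosmic <- make_kb(hotspots = hotspot_row(gene = "G1", codon = 100L))
  t6 <- auto_tags(make_var(), make_ann(), pf_of(), kb_cosmic, gene_meta_row(), cfg)
  expect_true("PM1" %in% t6$code)
})

test_that("PM2 and BA1 are mutually exclusive across a frequency grid", {
  cfg <- triage_config()
  v <- make_var(); ann <- make_ann(); gm <- gene_meta_row()
  grid <- c(NA, (0:100) / 1000)   # 0 .. 0.1
  for (f in grid) {
    tags <- auto_tags(v, ann, pf_of(exac = f), empty_kb(), gm, cfg)
    expect_false(all(c("PM2", "BA1") %in% tags$code), info = f)
    if (is.na(f) || f <= cfg$pm2_max_af) {
      expect_true("PM2" %in% tags$code, info = f)
    }
    if (!is.na(f) && f > cfg$ba1_min_af) {
      expect_true("BA1" %in% tags$code, info = f)
    }
  }
  # a frequency of 0.20 yields BA1 and not PM2
  t <- auto_tags(v, ann, pf_of(exac = 0.20), empty_kb(), gm, cfg)
  expect_identical(t$code, "BA1")
})

test_that("tag edits recompute the classification and round-trip", {
  a <- acmg_assessment(rbind(acmg_tag("PVS1", origin = "auto"),
                             acmg_tag("PM2", origin = "auto")))
  expect_identical(a$classification, "LP")
  # removing the auto PVS1 drops to VUS
  a2 <- edit_tags(a, remove = "PVS1")
  expect_identical(a2$classification, "VUS")
  expect_identical(a2$tags$code, "PM2")
  # adding functional evidence with PubMed support reaches P
  ps3 <- acmg_tag("PS3", origin = "manual", pubmed_ids = c("19483194"),
                  note = "functional assay")
  a3 <- edit_tags(a, add = ps3)
  expect_identical(a3$classification, "P")
  expect_identical(a3$tags$pubmed_ids[a3$tags$code == "PS3"], "19483194")
  # add then remove restores the original classification
  a4 <- edit_tags(a3, remove = "PS3")
  expect_identical(a4$classification, a$classification)
  expect_warning(edit_tags(a, remove = "BS4"), "not present")
})

test_that("assessments serialize to JSON and back", {
  a <- acmg_assessment(rbind(acmg_tag("PVS1", origin = "auto"),
                             acmg_tag("PS3", origin = "manual",
                                      pubmed_ids = c("1", "2"),
                                      note = "assay")))
  js <- acmg_to_json(a, "12:2001000:C>T")
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(parsed$variant_key, "12:2001000:C>T")
  expect_identical(parsed$classification, "P")
  b <- acmg_from_json(js)
  expect_identical(b$classification, a$classification)
  expect_setequal(b$tags$code, a$tags$code)
  expect_identical(b$tags$pubmed_ids[b$tags$code == "PS3"], "1,2")
})

test_that("tag strengths follow the code prefix", {
  expect_identical(acmg_strength(c("PVS1", "PS2", "PM6", "PP5", "BA1",
                                   "BS3", "BP7")),
                   c("very_strong", "strong", "moderate", "supporting",
                     "stand_alone_benign", "strong_benign",
                     "supporting_benign"))
  expect_error(acmg_strength("PVS2"), "unknown")
})
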