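cfg0 <- triage_config()

test_that("truncating variant in a loss-of-function gene earns gold with an audit trail", {
  v <- make_var(chrom = "12", pos = 2001000L, ref = "C", alt = "T")
  ann <- make_ann(gene = "ETV6", consequence = "nonsense", codon = 359L,
                  aa_ref = "R", aa_alt = "*")
  r <- assign_germline_medal(v, ann, pf_of(), no_pred(), empty_kb(),
                             gene_meta_row("ETV6", lof = TRUE), cfg0)
  expect_identical(r$medal, "GOLD")
  expect_identical(r$gate_status, "passed")
  expect_true("gold_truncating_lof" %in% r$reasons$rule_id)
})

test_that("exact silver-tier ClinVar match plus tolerated prediction is germline silver, somatic bronze", {
  v <- make_var(chrom = "9", pos = 500L, ref = "G", alt = "T")
  kb <- make_kb(curated = curated_row(chrom = "9", pos = 500, ref = "G",
                                      alt = "T", gene = "NOTCH1",
                                      call = "Pathogenic", stars = 1L))
  ann <- make_ann(gene = "NOTCH1", consequence = "missense", codon = 1350L,
                  aa_ref = "R", aa_alt = "L")
  pred <- pred_of(calls = c("tolerated", "tolerated"))
  g <- assign_germline_medal(v, ann, pf_of(), pred, kb,
                             gene_meta_row("NOTCH1"), cfg0)
  s <- assign_somatic_medal(v, ann, pred, kb, gene_meta_row("NOTCH1"), cfg0)
  expect_identical(g$medal, "SILVER")
  expect_true("silver_db_match" %in% g$reasons$rule_id)
  expect_identical(s$medal, "BRONZE")
})

test_that("frequency gate: boundary is <= and exceptions rescue", {
  v <- make_var()
  ann <- make_ann()
  pred <- pred_of(calls = c("damaging", "damaging"))
  gm <- gene_meta_row()
  medal_at <- function(f, kb = empty_kb()) {
    assign_germline_medal(v, ann, pf_of(exac = f), pred, kb, gm, cfg0)
  }
  # exactly at the cutoff passes; strictly greater fails
  expect_identical(medal_at(cfg0$max_af)$medal, "SILVER")
  expect_identical(medal_at(cfg0$max_af)$gate_status, "passed")
  at <- medal_at(0.002)
  expect_identical(at$medal, "UNKNOWN")
  expect_identical(at$gate_status, "failed_frequency")
  # IARC exact match rescues, and all rules then apply
  kb <- make_kb(curated = curated_row(source = "IARC_TP53", chrom = "1",
                                      pos = 1000, ref = "G", alt = "A",
                                      call = NA))
  resc <- medal_at(0.002, kb)
  expect_identical(resc$gate_status, "rescued_by_exception")
  expect_identical(resc$medal, "GOLD")   # IARC exact is itself gold-tier
  # absent frequency always passes
  expect_identical(medal_at(NA_real_)$gate_status, "passed")
})

test_that("disabling the gate makes medals invariant to all frequency fields", {
  cfg_off <- triage_config(max_af = "off")
  v <- make_var(); ann <- make_ann(); gm <- gene_meta_row()
  pred <- pred_of(calls = c("damaging", "damaging"))
  for (f in c(NA, 0, 0.002, 0.2, 1)) {
    r <- assign_germline_medal(v, ann, pf_of(exac = f), pred, empty_kb(),
                               gm, cfg_off)
    expect_identical(r$medal, "SILVER", info = f)
    expect_identical(r$gate_status, "passed", info = f)
  }
})

test_that("whitelist always medals, blacklist always blocks", {
  v <- make_var()
  ann <- make_ann()
  gm <- gene_meta_row("G1", lof = TRUE)
  wl <- assign_germline_medal(v, ann, pf_of(), no_pred(), empty_kb(), gm,
                              cfg0, whitelist = v$key)
  expect_identical(wl$medal, "GOLD")
  expect_identical(wl$gate_status, "whitelisted")
  # blacklist wins even over strong evidence
  ann2 <- make_ann(consequence = "nonsense", aa_alt = "*")
  bl <- assign_germline_medal(v, ann2, pf_of(), no_pred(), empty_kb(), gm,
                              cfg0, blacklist = v$key)
  expect_identical(bl$medal, "UNKNOWN")
  expect_identical(bl$gate_status, "blacklisted")
})

test_that("imperfect matches downgrade exactly one tier", {
  v <- make_var(pos = 700L)
  ann <- make_ann(codon = 12L, aa_ref = "G", aa_alt = "S")
  gm <- gene_meta_row()
  # gold-tier record at same codon, different amino acid -> silver
  kb_gold <- make_kb(curated = curated_row(gene = "G1",
                                           protein_change = "p.Gly12Asp",
                                           call = "Pathogenic", stars = 3L))
  g <- assign_germline_medal(v, ann, pf_of(), no_pred(), kb_gold, gm, cfg0)
  expect_identical(g$medal, "SILVER")
  expect_true("silver_imperfect_gold_db" %in% g$reasons$rule_id)
  # silver-tier record at same codon, different amino acid -> bronze
  kb_silver <- make_kb(curated = curated_row(source = "ALSOD", gene = "G1",
                                             protein_change = "p.Gly12Asp",
                                             call = "Pathogenic"))
  b <- assign_germline_medal(v, ann, pf_of(), no_pred(), kb_silver, gm, cfg0)
  expect_identical(b$medal, "BRONZE")
  expect_true("bronze_imperfect_silver_db" %in% b$reasons$rule_id)
})

test_that("missing gene metadata is treated as non-LoF with a warning, never silently gold", {
  v <- make_var()
  ann <- make_ann(consequence = "nonsense", aa_alt = "*")
  expect_warning(
    r <- assign_germline_medal(v, ann, pf_of(), no_pred(), empty_kb(),
                               NULL, cfg0),
    "non-loss-of-function")
  expect_identical(r$medal, "SILVER")   # truncating in non-LoF gene
})

test_that("somatic medal never consults germline-only resources", {
  v <- make_var(pos = 800L)
  # strong ClinVar evidence, no somatic evidence
  kb <- make_kb(curated = curated_row(chrom = "1", pos = 800, ref = "G",
                                      alt = "A", call = "Pathogenic",
                                      stars = 4L))
  ann <- make_ann()
  s <- assign_somatic_medal(v, ann, no_pred(), kb, gene_meta_row(), cfg0)
  expect_identical(s$medal, "UNKNOWN")
})

test_that("somatic hotspot matching distinguishes observed from novel amino acids", {
  v <- make_var(pos = 900L)
  gm <- gene_meta_row()
  kb <- make_kb(hotspots = hotspot_row(gene = "G1", codon = 12L,
                                       tumor_count = 4000L,
                                       aa_changes = "S,D"))
  ann_obs <- make_ann(codon = 12L, aa_alt = "S")
  ann_new <- make_ann(codon = 12L, aa_alt = "C")
  expect_identical(assign_somatic_medal(v, ann_obs, no_pred(), kb, gm, cfg0)$medal,
                   "GOLD")
  expect_identical(assign_somatic_medal(v, ann_new, no_pred(), kb, gm, cfg0)$medal,
                   "SILVER")
  # germline hotspot rule is codon-level regardless of amino acid
  g <- assign_germline_medal(v, ann_new, pf_of(), no_pred(), kb, gm, cfg0)
  expect_identical(g$medal, "GOLD")
})

test_that("prediction aggregation matches a brute-force enumeration of its definition", {
  cfg <- triage_config()
  bf <- function(calls, revel) {
    nonunk <- calls[calls != "unknown"]
    n <- length(nonunk)
    nd <- sum(nonunk == "damaging")
    if (!is.na(revel) && revel >= cfg$revel_damaging) return("damaging")
    if (n > 0 && nd > n / 2) return("damaging")
    if (n > 0 && nd == 0 && (is.na(revel) || revel < cfg$revel_damaging)) {
      return("tolerated")
    }
    "unknown"
  }
  opts <- c("damaging", "tolerated", "unknown")
  for (len in 0:4) {
    combos <- if (len == 0) list(character(0)) else {
      grid <- do.call(expand.grid, c(rep(list(opts), len),
                                     stringsAsFactors = FALSE))
      lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ],
                                                     use.names = FALSE))
    }
    for (calls in combos) {
      for (revel in c(NA_real_, 0.2, 0.8)) {
        expect_identical(
          aggregate_prediction(pred_of(calls = calls, revel = revel), cfg),
          bf(calls, revel),
          info = paste(paste(calls, collapse = ","), revel))
      }
    }
  }
})

test_that("adding evidence never lowers the germline medal (monotonicity)", {
  set.seed(51)
  medal_rank <- function(m) match(m, c("GOLD", "SILVER", "BRONZE", "UNKNOWN"))
  v <- make_var(pos = 1200L)
  gm_nl <- gene_meta_row()
  base_ann <- make_ann(codon = 20L, aa_ref = "G", aa_alt = "S")
  base <- assign_germline_medal(v, base_ann, pf_of(), no_pred(), empty_kb(),
                                gm_nl, cfg0)
  additions <- list(
    db = function() {
      kb <- make_kb(curated = curated_row(chrom = "1", pos = 1200, ref = "G",
                                          alt = "A", gene = "G1",
                                          call = "Pathogenic", stars = 3L))
      assign_germline_medal(v, base_ann, pf_of(), no_pred(), kb, gm_nl, cfg0)
    },
    hotspot = function() {
      kb <- make_kb(hotspots = hotspot_row(gene = "G1", codon = 20L))
      assign_germline_medal(v, base_ann, pf_of(), no_pred(), kb, gm_nl, cfg0)
    },
    damaging = function() {
      assign_germline_medal(v, base_ann, pf_of(),
                            pred_of(calls = c("damaging", "damaging")),
                            empty_kb(), gm_nl, cfg0)
    })
  for (nm in names(additions)) {
    withcal <- additions[[nm]]()
    expect_lte(medal_rank(withcal$medal), medal_rank(base$medal), label = nm)
  }
  # adding only a blacklist entry forces UNKNOWN
  bl <- assign_germline_medal(v, base_ann, pf_of(), no_pred(), empty_kb(),
                              gm_nl, cfg0, blacklist = v$key)
  expect_identical(bl$medal, "UNKNOWN")
})

test_that("configuration invariants are enforced", {
  expect_error(triage_config(pm2_max_af = 0.01, max_af = 0.001),
               "pm2_max_af <= max_af")
  expect_error(triage_config(ba1_min_af = 1.5), "frequency")
  expect_error(triage_config(hotspot_min_tumors = -1), "integer")
  expect_identical(triage_config(max_af = "off")$max_af, NA_real_)
})
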