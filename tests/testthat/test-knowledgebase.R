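test_that("snapshot loading builds a manifest matching the generator's", {
  s <- get_suite()
  kb <- load_snapshot(file.path(s$dir, "kb"))
  count_rows <- function(f) {
    length(readLines(file.path(s$dir, "kb", f))) - 1L
  }
  expect_identical(kb$manifest$curated, count_rows("curated.tsv"))
  expect_identical(kb$manifest$hotspots, count_rows("hotspots.tsv"))
  expect_identical(kb$manifest$frequencies, count_rows("frequencies.tsv"))
  expect_identical(kb$manifest$predictions, count_rows("predictions.tsv"))
})

test_that("an empty directory is a valid empty knowledgebase", {
  kb <- empty_kb()
  v <- make_var()
  expect_identical(nrow(match_variant(kb, v, gene = "G1", codon = 10L)), 0L)
  expect_false(is_hotspot(kb, "G1", 10L)$is_hotspot)
  expect_true(all(is.na(kb_frequencies(kb, v$key))))
  expect_identical(kb_predictions(kb, v$key)$calls, character(0))
})

test_that("schema violations are load errors naming the problem", {
  expect_error(make_kb(curated = curated_row(chrom = "1", pos = 100, ref = "A",
                                             alt = "G", stars = 5L)),
               "stars")
  bad <- curated_row(chrom = "1", pos = 100, ref = "A", alt = "G")
  bad$extra_col <- 1
  expect_error(make_kb(curated = bad), "extra_col")
  expect_error(make_kb(curated = curated_row(source = "IARC_TP53", chrom = "1",
                                             pos = 100, ref = "A", alt = "G",
                                             stars = 2L)),
               "CLINVAR")
  expect_error(make_kb(hotspots = hotspot_row(tumor_count = 0L)), "tumor_count")
  expect_error(make_kb(hotspots = rbind(hotspot_row(), hotspot_row())),
               "unique")
})

test_that("duplicate curated keys keep the last record with a warning", {
  cu <- rbind(curated_row(chrom = "1", pos = 100, ref = "A", alt = "G",
                          call = "Benign", stars = 1L),
              curated_row(chrom = "1", pos = 100, ref = "A", alt = "G",
                          call = "Pathogenic", stars = 3L))
  expect_warning(kb <- make_kb(curated = cu), "last wins")
  m <- match_variant(kb, make_var(pos = 100L, ref = "A", alt = "G"),
                     gene = "G1")
  expect_identical(nrow(m), 1L)
  expect_identical(m$call, "P")
})

test_that("match grades agree with a quadratic brute-force oracle", {
  set.seed(41)
  n <- 200
  genes <- sprintf("g%02d", sample(1:30, n, TRUE))
  codons <- sample(1:40, n, TRUE)
  # unique genomic positions so (source, genomic_key) never collides and
  # record identities survive the loader's last-wins dedup untouched
  pos <- sample(seq(1000, 5000, by = 10), n, replace = FALSE)
  aa <- c("A", "R", "G", "S", "D", "V")
  # curated records: mix of genomic, protein-only, and both
  recs <- lapply(1:n, function(i) {
    has_gen <- runif(1) < 0.7
    has_prot <- !has_gen || runif(1) < 0.5
    curated_row(source = sample(c("CLINVAR", "ALSOD", "IARC_TP53"), 1),
                chrom = if (has_gen) "1" else NA,
                pos = if (has_gen) pos[i] else NA,
                ref = if (has_gen) "A" else NA,
                alt = if (has_gen) sample(c("G", "T"), 1) else NA,
                gene = genes[i],
                protein_change = if (has_prot) {
                  render_protein_change(sample(aa, 1), codons[i],
                                        sample(aa, 1), "three")
                } else NA,
                call = "Pathogenic",
                stars = NA)
  })
  cu <- do.call(rbind, recs)
  kb <- make_kb(curated = cu)
  pp_all <- parse_protein_change(ifelse(is.na(cu$protein_change), "",
                                        cu$protein_change))
  # brute-force grade of one record against one query
  bf_grade <- function(i, qpos, qgene, qcodon, qa_ref, qa_alt) {
    r <- cu[i, ]
    pp <- pp_all[i, ]
    expected <- "NONE"
    if (!is.na(r$pos) && r$pos == qpos) {
      expected <- if (r$alt == "G") "EXACT_GENOMIC" else "SAME_POSITION_DIFF_ALLELE"
    }
    if (expected != "EXACT_GENOMIC" && pp$status == "full" &&
        r$gene == qgene && pp$codon == qcodon) {
      if (pp$aa_alt == qa_alt && pp$aa_ref == qa_ref) {
        expected <- "EXACT_PROTEIN"
      } else if (expected == "NONE") {
        expected <- "SAME_CODON_DIFF_AA"
      }
    }
    expected
  }
  for (q in 1:200) {
    qpos <- sample(seq(1000, 5000, by = 10), 1)
    qgene <- sprintf("g%02d", sample(1:30, 1))
    qcodon <- sample(1:40, 1)
    qa_ref <- sample(aa, 1); qa_alt <- sample(aa, 1)
    v <- make_var(pos = qpos, ref = "A", alt = "G")
    got <- match_variant(kb, v, gene = qgene, codon = qcodon,
                         aa_ref = qa_ref, aa_alt = qa_alt)
    expected <- vapply(1:n, bf_grade, "", qpos = qpos, qgene = qgene,
                       qcodon = qcodon, qa_ref = qa_ref, qa_alt = qa_alt)
    exp_df <- data.frame(record_id = which(expected != "NONE"),
                         grade = expected[expected != "NONE"])
    got_df <- got[order(got$record_id), c("record_id", "grade")]
    rownames(got_df) <- NULL
    expect_identical(got_df, exp_df,
                     info = sprintf("query %s/%s c%d %s>%s", qpos, qgene,
                                    qcodon, qa_ref, qa_alt))
  }
})

test_that("hotspot determination recovers the count threshold by sweep", {
  hs <- do.call(rbind, lapply(1:25, function(k) {
    hotspot_row(gene = sprintf("h%02d", k), codon = 10L, tumor_count = k)
  }))
  kb <- make_kb(hotspots = hs)
  cfg <- triage_config()
  qualifies <- vapply(1:25, function(k) {
    is_hotspot(kb, sprintf("h%02d", k), 10L, cfg)$is_hotspot
  }, logical(1))
  expect_identical(min(which(qualifies)), as.integer(cfg$hotspot_min_tumors))
  expect_false(qualifies[cfg$hotspot_min_tumors - 1L])
  expect_true(qualifies[cfg$hotspot_min_tumors])
})

test_that("curated PCGP hotspots qualify regardless of count; uncurated do not", {
  kb <- make_kb(hotspots = rbind(
    hotspot_row(source = "PCGP", gene = "a", tumor_count = 2L, curated_flag = 1L),
    hotspot_row(source = "PCGP", gene = "b", tumor_count = 500L, curated_flag = 0L)))
  expect_true(is_hotspot(kb, "a", 12L)$is_hotspot)
  expect_false(is_hotspot(kb, "b", 12L)$is_hotspot)
})

test_that("frequency-gate exception requires an exact, highly curated match", {
  v <- make_var(pos = 100L, ref = "A", alt = "G")
  cfg <- triage_config()
  q <- function(kb) {
    m <- match_variant(kb, v, gene = "G1", codon = 10L, aa_ref = "G",
                       aa_alt = "S")
    frequency_gate_exception(m, cfg)$rescued
  }
  exact <- function(call, stars = NA, source = "CLINVAR") {
    make_kb(curated = curated_row(source = source, chrom = "1", pos = 100,
                                  ref = "A", alt = "G", call = call,
                                  stars = stars))
  }
  expect_true(q(exact("Pathogenic", 3L)))
  expect_true(q(exact("Pathogenic", 2L)))
  expect_false(q(exact("Pathogenic", 1L)))
  expect_false(q(exact("Benign", 3L)))
  expect_true(q(exact(NA, NA, source = "IARC_TP53")))
  # imperfect match to IARC does not rescue
  kb <- make_kb(curated = curated_row(source = "IARC_TP53", chrom = "1",
                                      pos = 100, ref = "A", alt = "T",
                                      call = NA))
  expect_false(q(kb))
})

test_that("snapshot round-trips through write_snapshot with identical answers", {
  s <- get_suite()
  kb1 <- load_snapshot(file.path(s$dir, "kb"))
  d2 <- tempfile("rt")
  write_snapshot(kb1, d2)
  kb2 <- load_snapshot(d2)
  expect_identical(kb1$manifest, kb2$manifest)
  v <- make_var(chrom = "1", pos = 1150100L, ref = "G", alt = "A")
  m1 <- match_variant(kb1, v, gene = "NRAS", codon = 12L, aa_ref = "G",
                      aa_alt = "S")
  m2 <- match_variant(kb2, v, gene = "NRAS", codon = 12L, aa_ref = "G",
                      aa_alt = "S")
  expect_identical(m1[, c("source", "grade", "call", "stars")],
                   m2[, c("source", "grade", "call", "stars")])
  expect_identical(is_hotspot(kb1, "NRAS", 12L)$record$tumor_count,
                   is_hotspot(kb2, "NRAS", 12L)$record$tumor_count)
  expect_identical(kb_frequencies(kb1, "7:708000:A>G"),
                   kb_frequencies(kb2, "7:708000:A>G"))
})
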