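# varmedal

Rule-based triage and classification of germline sequence variants for
disease-gene panel review. Starting from a VCF, `varmedal` decomposes and
normalizes alleles, filters them to a gene panel, applies splice-aware
consequence adjustment, matches each variant against tab-delimited
snapshots of curated variant databases, somatic hotspot tables,
population allele frequencies and in silico damage predictions, and then:

* assigns a germline **medal** — gold, silver, bronze, or unknown — as a
  decreasing-confidence triage rank, with an auditable trail of every
  fired rule (and a separate, simpler somatic medal);
* auto-generates the derivable **ACMG/AMP evidence tags** (PVS1, PS1,
  PM1, PM2, PM4, PM5, BA1) and computes the five-tier classification
  (P / LP / VUS / LB / B) from the published combining rules, shipped as
  an auditable rule table.

It is written for analysts and bioinformaticians who triage germline
findings in rare-disease or cancer-predisposition cohorts and want the
mechanical part of ACMG review — frequency gating, database lookup,
hotspot matching, tag assembly — automated, deterministic, and auditable.

## The rules in brief

A variant with ExAC non-TCGA allele frequency > 0.001 receives no medal
unless rescued by an exact match in IARC TP53 or in ClinVar (P/LP, ≥ 2
review stars). Gold goes to truncating variants (nonsense, frameshift,
canonical splice) in loss-of-function disease genes, exact matches to
highly curated databases, and somatic hotspots (COSMIC codons seen in
≥ 10 tumors, or curated PCGP hotspots). Silver goes to in-frame indels,
truncations in other genes, predicted-damaging variants, matches to
additional databases, and *imperfect* matches (same position different
allele, same codon different amino acid) to gold-tier databases —
imperfect matches always cost exactly one tier. Bronze goes to
predicted-tolerated variants and imperfect silver-tier matches.
Whitelists always medal; blacklists never do. Every threshold is a
`triage_config()` parameter and the frequency gate can be disabled.

See `vignette("germline-variant-triage")` for the full model, parameter
rationale, and known limitations.

## Worked example

The package ships a deterministic generator that produces a complete
synthetic input set (VCF, panel, annotations, exon models, knowledgebase
snapshot, white/blacklist) plus a ground-truth manifest:

```r
library(varmedal)
d <- tempfile()
generate_suite(seed = 1, out_dir = d)
res <- run_pipeline(
  vcf = file.path(d, "suite.vcf"), panel = file.path(d, "panel.tsv"),
  annotations = file.path(d, "annotations.tsv"),
  exons = file.path(d, "exons.tsv"), kb_dir = file.path(d, "kb"),
  gene_meta = file.path(d, "gene_meta.tsv"),
  whitelist = file.path(d, "whitelist.txt"),
  blacklist = file.path(d, "blacklist.txt"))
print(res)
#> Triage result (knowledgebase 'kb')
#>   VCF records: 40  alleles: 41  (symbolic skipped: 1)
#>   variants: 40 -> on panel: 38 -> coding/splice: 36 -> gate passed: 29 -> medaled: 24
#>   germline medals: GOLD=12 SILVER=8 BRONZE=4 UNKNOWN=12
```

The funnel reads: 40 VCF records yielded 41 ALT alleles, one symbolic
allele was skipped, 38 of the 40 variants fell in panel genes, 36
survived the coding/splice filter, 29 passed the frequency gate (or were
whitelisted/rescued), and 24 earned a medal. Each row carries its full
audit:

```r
variant_audit(res, "12:2001000:C>T")
#> 12:2001000:C>T (ETV6, TR_ETV6)
#>   consequence: nonsense  protein: R359*
#>   ExAC non-TCGA: absent  prediction: unknown
#>   germline medal: GOLD (gate passed)
#>     gold_truncating_lof[nonsense in loss-of-function gene ETV6]
#>   somatic medal: GOLD
#>   ACMG: [PVS1,PM2] -> LP
#>   knowledgebase: kb
```

A nonsense variant at codon 359 of a loss-of-function leukemia gene:
gold medal for truncation in a loss-of-function gene, automatic PVS1 and
PM2 tags (absent from ExAC non-TCGA), and a likely-pathogenic five-tier
call — which an analyst can then edit (`edit_tags()`), e.g. adding PS3
with PubMed support to reach pathogenic. `write_reports()` emits the
table as TSV and JSON.

A command-line driver with the same behavior is installed at
`inst/cli/varmedal.R`:

```sh
Rscript inst/cli/varmedal.R --vcf suite.vcf --panel panel.tsv \
  --annotations annotations.tsv --exons exons.tsv --kb kb \
  --gene-meta gene_meta.tsv --out triage --variant-key "12:2001000:C>T"
```

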