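---
title: "Germline variant triage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germline variant triage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmedal)
```

## The problem

Exome or genome sequencing of a single individual yields tens of thousands
to millions of germline variants, of which at most a handful are plausible
causes of a rare disease such as a pediatric cancer predisposition
syndrome. `varmedal` implements a rule-based triage of that haystack: it
reduces a VCF to the variants worth an expert's attention, ranks them with
a three-tier **medal** (gold, silver, bronze — decreasing strength of
pathogenicity evidence; *unknown* when no rule fires), and pre-populates
the ACMG/AMP evidence tags so that the final five-tier classification
(P / LP / VUS / LB / B) needs only analyst review, not manual assembly.

Everything is per allele: multi-allelic VCF records are decomposed before
any downstream step, symbolic alleles (`<DEL>`, breakends, `*`) are
skipped and counted, and each allele pair is anchor-trimmed so that keys
derived from VCFs match keys derived from knowledgebase snapshots.

## The processing funnel

1. **VCF ingestion** (`read_vcf`) — decomposition, normalization,
   canonical chromosome names (no `chr` prefix internally).
2. **Gene-panel filter** (`filter_to_panel`) — whole-gene genomic
   intervals in BED convention (0-based, half-open); a variant's full REF
   span is intersected, so deletions crossing a panel edge are retained.
   Whole-gene rather than exonic footprints were chosen because the
   functional filter downstream removes non-coding hits anyway.
3. **Annotation** (`load_annotations`) — a tab-delimited table in the
   dialect of common effect predictors is consumed, not computed; protein
   notations run through the nomenclature parser.
4. **Splice-aware adjustment** (`reclassify_splice`) — silent and missense
   calls at exon boundaries are promoted to `splice_region` (audited in
   `original_consequence`), because such variants can disrupt splicing
   despite an innocuous protein-level annotation.
5. **Functional filter** (`filter_functional`) — coding and splice-related
   classes are retained, **including silent variants**, which in rare
   cases are pathogenic splice variants; UTR, intronic, intergenic and
   unclassified annotations are dropped.
6. **Medals** (`assign_germline_medal`, `assign_somatic_medal`) and
   **ACMG tags** (`auto_tags`, `classify_acmg`).

## The germline medal rules

Evaluation order, with every fired rule recorded in the reason trail:

* **Blacklist** (exact genomic key): never medaled, regardless of other
  evidence. **Whitelist**: always medaled; we grant gold because a
  whitelist encodes committee knowledge, the highest-trust source.
* **Frequency gate**: a variant whose ExAC non-TCGA allele frequency
  exceeds `max_af` (default 0.001, `<=` semantics: exactly 0.001 passes)
  is set to *unknown* — unless it has an exact (genomic or protein) match
  in the IARC TP53 database, or in ClinVar with a P/LP call and at least
  `clinvar_min_stars` (default 2) review stars. The exception retains
  founder variants and partially penetrant alleles. The non-TCGA subset
  matters because a cancer cohort is enriched for the very predisposition
  alleles being sought. Once rescued, *all* medal rules apply (not only
  the rescuing match); the rescue is recorded in the reason trail.
  Absent frequency and a frequency of 0 both pass: absence means "not
  observed", distinct from zero only in provenance.
* **Gold**: truncating consequence (nonsense, frameshift, canonical
  splice) in a gene whose disease mechanism is loss of function; exact
  match to a highly curated database (IARC TP53; ClinVar P/LP with
  ≥ `clinvar_min_stars`; ASU TERT; ARUP MEN2; NHGRI BIC; committee P/LP);
  somatic hotspot (COSMIC codon with ≥ `hotspot_min_tumors` tumors,
  default 10, or a curated PCGP hotspot).
* **Silver**: in-frame indel; truncating in a non-loss-of-function gene;
  predicted damaging; exact match to a silver-tier database (ClinVar P/LP
  below the star threshold, BRCA Share, ALSoD, LOVD APC/MSH2, RB1);
  **imperfect** match (same position different allele, or same codon
  different amino acid) to a gold-tier database.
* **Bronze**: predicted tolerated; imperfect match to a silver-tier
  database.
* Conflicts resolve as *highest medal wins*, with all fired rules kept —
  the tier diagram itself does not state a conflict rule, so we chose the
  monotone one. The imperfect-match downgrade is always exactly one tier;
  a "typically one tier" rule would be non-deterministic.

The **somatic medal** is a deliberately simpler, separate call that never
consults germline-only resources: gold for a hotspot whose observed
amino-acid changes include the variant's (or are unrecorded) or a
truncating variant in a loss-of-function gene, silver for a same-codon
hotspot with a different amino acid or a damaging prediction, bronze for
tolerated, otherwise unknown. The two medals can legitimately differ — a
missense with a ClinVar match but tolerated predictions is germline
silver and somatic bronze.

## Database matching at graded specificity

`match_variant` grades every curated record sharing the variant's genomic
position or (gene, codon):

`EXACT_GENOMIC > EXACT_PROTEIN > SAME_POSITION_DIFF_ALLELE >
SAME_CODON_DIFF_AA`

Protein-level matching requires the same gene and codon number but *not*
the same transcript: locus-specific databases rarely state transcripts,
and requiring them would cost recall that the grade system already prices
in. Codon-numbering drift across transcripts is therefore an accepted,
logged risk. Indels are anchor-trimmed on both sides of the comparison;
no reference-FASTA left-alignment is performed, which can in principle
miss a match for an indel normalized differently upstream — a documented
limitation rather than a silent one.

## Prediction aggregation

Categorical calls from damage-prediction algorithms plus a REVEL score
aggregate as: **damaging** if REVEL ≥ `revel_damaging` (default 0.5) or a
strict majority of the non-unknown categorical calls say damaging (an
absolute count can be configured instead); **tolerated** if at least one
categorical call is present, none says damaging, and REVEL (if present)
is below the cutoff; otherwise **unknown**. A lone low REVEL score is
deliberately *unknown*, not tolerated: absence of a damaging signal from
one score is weaker evidence than concordant tolerated calls.

## Automated ACMG tags and the five-tier calculation

Seven criteria are automated, exactly the set that can be derived from
the pipeline's own evidence: PVS1 (truncating in a loss-of-function
gene), PM1 (COSMIC hotspot), PM2 (ExAC non-TCGA absent or ≤ 0.0001), BA1
(> 5%), PM4 (in-frame indel), PS1 (identical amino-acid change as a P/LP
ClinVar/committee variant), PM5 (different change at the same codon).
PS1 versus PM5 is decided purely by the match grade. PM2 and BA1 are
mutually exclusive by construction. All other criteria (de novo,
segregation, functional data, ...) are manual-entry only, via
`edit_tags`, which preserves provenance and PubMed IDs and recomputes the
classification on every edit.

The combining rules ship as a human-reviewable data table
(`inst/extdata/acmg_combining_rules.tsv`), one row per rule with minimum
tag counts per strength class, so the transcription of the published
rules is itself auditable. When a pathogenic-side and a benign-side rule
both fire the classification is VUS — the strictest reading of the
guideline's conflict clause, chosen because an automated tool should
surface conflicts, not adjudicate them.

## Nomenclature standardization

Curated databases are dirty by design, so the protein parser accepts
three- and one-letter codes, an optional `p.` prefix and parentheses,
`=` for synonymous, and five stop spellings (`Ter`, `Term`, `Stop`, `X`,
`*`); `X` is a stop only in the alternate position. When the grammar
fails, a codon number is still extracted (`codon_only`) so partial
records remain usable for same-codon matching; nucleotide-level notation
fails outright without salvage. Parsing never raises. Pathogenicity
vocabulary maps onto B/LB/VUS/LP/P through an editable shipped table;
anything uncovered is `unmapped`, and no label can reach P/LP unless it
contains the substring "pathogenic" — dirty labels must never inflate
pathogenicity.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `max_af` | 0.001 (disable-able) | allele fraction | germline medal frequency gate (≤ passes) |
| `pm2_max_af` | 0.0001 | allele fraction | PM2 ceiling |
| `ba1_min_af` | 0.05 | allele fraction | BA1 floor (strictly greater fires) |
| `hotspot_min_tumors` | 10 | tumors | COSMIC hotspot threshold |
| `clinvar_min_stars` | 2 | stars | "highly curated" ClinVar (gold tier, gate rescue) |
| `splice_window_donor` | 3 | exonic bases | promotion window at the donor edge |
| `splice_window_acceptor` | 1 | exonic bases | promotion window at the acceptor edge |
| `revel_damaging` | 0.5 | score | REVEL damaging cutoff |
| `splice_region_truncating` | FALSE | — | whether promoted calls count as truncating |

The splice windows are asymmetric because the donor consensus extends
further into the exon than the acceptor consensus; the canonical
silent-at-exon-end examples sit at 3′ exon ends. Both windows are exposed
because no single published value governs them. Promoted `splice_region`
calls are retained for review but are **not** treated as truncating by
default: promotion flags *possible* splice impact, which is weaker
evidence than a canonical splice-site call; the toggle exists for groups
that disagree. PCGP hotspots carry an explicit curated flag in the
snapshot rather than a count threshold, because only the COSMIC threshold
has a published value; the flag externalizes that curation decision to
the snapshot.

## The synthetic data generator

`generate_suite()` emits a complete, deterministic input set — VCF,
panel, gene metadata, exon models, annotation table, knowledgebase
snapshot, white/blacklist — plus a JSON manifest of expected outcomes.
Five fixed archetypes anchor the worked examples: a nonsense truncation
at codon 359 of a loss-of-function leukemia gene (gold; PVS1 + PM2 → LP),
a codon-12 hotspot missense with a same-codon curated pathogenic record
(gold; PM1/PM2/PM5), a missense with an exact low-star ClinVar match but
tolerated predictions (germline silver, somatic bronze), a silent variant
at an exon donor edge (promoted and retained), and an ALS-database
missense (silver). Around them, coverage rows exercise every medal rule,
gate status (each at least three times), variant type (SNV, insertion,
deletion, MNV, complex), a multi-allelic record, a symbolic allele, and a
padded record that only matches after normalization.

Expected outcomes in the manifest are computed by independent
decision-table oracles (`oracle_germline_medal` and friends) that map
evidence feature flags straight onto the tier diagram — the engines under
test are never consulted when a manifest is built. `generate_rule_battery()`
samples feature combinations at random (500 variants in the regression
suite) and the pipeline must agree with the oracle exactly.

What the generator does **not** emulate: realistic allele-frequency
spectra, mutational signatures, linkage between variants, genotype
quality, or the messiness of real annotation pipelines (multiple
overlapping genes, NMD-escape annotation, versioned transcripts). Passing
tests therefore demonstrate that the rule logic is implemented exactly as
specified, not that the rules themselves have clinical sensitivity or
specificity on real cohorts — the latter depends on the knowledgebase
snapshots supplied at run time, and classifications drift with database
versions, which is why the snapshot label is stamped on every output row.

## Numerical and degenerate-input choices

Frequency comparisons are exact floating-point comparisons against the
configured thresholds; sweep grids in the tests are constructed as
integer ratios so grid points land exactly on the thresholds. Transcript
ties in most-severe selection break lexicographically; matched records
order by source then grade, so output is byte-deterministic. Degenerate
inputs are contracts, not crashes: an empty VCF body is an empty result,
an empty snapshot directory is a valid knowledgebase answering "no match"
everywhere, a missing gene-metadata record demotes to
non-loss-of-function with a warning (never silently gold), and an
unparseable protein field keeps its annotation with a failed-parse flag.

Problem sizes in the shipped tests — a 40-variant archetype suite, a
500-variant randomized battery, 200×200 match-oracle comparisons, and
roughly 1,500 tag subsets for the combining-rule enumeration — were
chosen as the smallest sizes that exercise every rule path at least
three times; the whole suite runs in about a minute.

## Known limitations

* Anchor-trimming only; no FASTA-aware left alignment (see above).
* Per-variant scope: zygosity and compound heterozygosity in
  autosomal-recessive genes are patient-level judgments, so genotypes are
  carried through opaquely for the sign-out note but never interpreted.
* GRCh38 input is a labeled pass-through; coordinates must already be
  GRCh37-equivalent.
* Damage predictions are consumed from snapshots and typically exist only
  for non-silent SNVs; indels rely on their protein-class rules instead.
* A misannotated somatic hotspot in a snapshot will inflate a medal; the
  audit trail names the record so review can catch it.
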