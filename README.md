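# cmpburden

Variant prioritization and rare-variant case–control burden testing for
whole-genome sequencing studies of early-onset cardiomyopathy (CMP).

Over half of childhood CMP cases are gene-elusive on clinical panel
testing. WGS adds three searchable spaces — copy-number variants, new
candidate genes, and the promoters/enhancers of known CMP genes — each of
which needs a disciplined filter cascade before any case–control claim can
be made. `cmpburden` implements those cascades and the statistics behind
them, for statistical geneticists and variant-curation teams who want the
filters, boundaries and burden arithmetic to be explicit, tested code
rather than a supplementary-methods paragraph.

## What it computes

For each gene *g*, carriers are counted once per sample and laid out as a
2×2 table (a = carrier cases, b = non-carrier cases, c = carrier controls,
d = non-carrier controls). The burden fit reports:

* **Haldane–Anscombe corrected odds ratio**
  OR = (a+½)(d+½) / ((b+½)(c+½)), finite even with zero cells;
* **Woolf 95% CI** on the corrected cells:
  exp(ln OR ± 1.96·√(Σ 1/(cell+½)));
* two-sided **Fisher exact p** on the uncorrected table
  (minimum-likelihood rule, log-space enumeration);
* **Benjamini–Hochberg q** across genes, after dropping genes with zero
  carriers everywhere;
* a two-sided **exact binomial test** with prior 9/84 for sarcomere-gene
  enrichment among prioritized variants.

Around the statistics sit the cascades: site QC (PASS, depth ≥ 10×), the
coding rules (gnomAD MAF < 0.01%, LOFTEE-style high-confidence LoF, splice
delta ≥ 0.5, ≥ 5-tool missense majority, zygosity–inheritance concordance,
ClinVar gating for Tier 2/secondary genes), two-caller CNV consensus
(≥ 50% reciprocal overlap, > 1 kb, < 70% telomere/centromere/segdup,
< 30% CN-prone, < 1% panel frequency), and the regulatory cascade
(Ensembl Regulatory Build overlap, 3-of-4 TFBS-alteration consensus,
Popmax AF < 0.1%, ≥ 1.5% cohort-frequency exclusion, per-gene OR ≥ 1.3,
restricted to gene-elusive cases). A seeded synthetic-cohort generator
with planted gene-level enrichment exercises everything end to end.

## Worked example

The four reference gene-level burden tables are reconstructed from their
printed OR/CI values by a brute-force oracle (`worked_example_tables()`
scans all carrier pairs a ≤ 30, c ≤ 30 and requires a unique simultaneous
match), then refit:

```r
library(cmpburden)
tabs <- worked_example_tables()
fit <- cmp_burden(vapply(tabs, `[[`, 0L, "a"),
                  vapply(tabs, `[[`, 0L, "c"),
                  n_cases = 209, n_controls = 1326)
fit
#> Gene-level carrier burden: 4 genes, 209 cases vs 1326 controls
#>  gene          carriers   OR       CI        p        q
#>  FKTN   4/209 vs 0/1326 58.1 3.1-1083 0.000335  0.00067
#>  DTNA 12/209 vs 12/1326  6.7   3.0-15 1.81e-05 7.24e-05
#>  DSC2   2/209 vs 0/1326 32.0  1.5-668   0.0185   0.0246
#>  DSG2   2/209 vs 1/1326 10.6   1.4-81   0.0504   0.0504
```

Four carrier cases of FKTN against zero carrier controls give a corrected
odds ratio of 58.1 with an interval spanning 3.1–1083 — enormous but
honest about its width; all four genes clear the OR ≥ 1.3 prioritization
gate, and the q column shows the FDR over the tested genes.

A full synthetic run, from cohort generation through prioritization to
the tally:

```r
pp <- run_pipeline(config = sim_config(seed = 1))
pp
#> Cardiomyopathy WGS prioritization pipeline
#>   cases: 209, controls: 1326
#>   coding_positive        72 (34.4%)
#>   cnv_positive           10 (4.8%)
#>   candidate_lof          11 (5.3%)
#>   regulatory_positive    50 (23.9%)
#>   gene_elusive          131 (62.7%)
#>   multiple_coding         4 (1.9%)
#>   multiple_regulatory    21 (10.0%)
#>   both_types             24 (11.5%)
#>   multiple_any           40 (19.1%)
#>   prioritized regulatory candidates: 64
```

The counts are per-case verdicts: 72 of 209 simulated cases carry a
retained pathogenic coding variant (the generator plants at 37%; QC noise
accounts for the difference), 131 are gene-elusive, and 50 of those carry
a prioritized regulatory variant in a gene passing the OR gate.
`pp$burden` holds the gene-level fit (`coef`, `confint`, `plot` give the
ORs, intervals and a forest plot), `pp$regulatory` the flagged candidate
table, and `attr(pp$regulatory, "gene_or")` the per-gene carrier counts.

See the vignette (`vignettes/cardiomyopathy-burden.Rmd`) for the model,
every filter boundary, and the design choices.

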