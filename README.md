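# nbsval

Analytical validation tooling for small targeted NGS panels of the kind
used in newborn bloodspot screening: a laboratory that sequences a few
tens of kilobases of exonic target from dried blood spots (DBS) needs to
show that its pipeline calls variants correctly against high-confidence
truth sets, that DBS results agree with venous blood (VB) results from
the same individuals, that per-sample coverage supports clinical
interpretation, and that the workflow meets screening turnaround and
throughput demands. `nbsval` implements that computational validation
end to end, plus a fully seeded synthetic-data generator so the whole
pipeline can be exercised — and its accounting proven exact — without
any patient data.

## What it computes

* **Variant canonicalization** — multi-allelic decomposition,
  left-align/trim normalization to the unique leftmost parsimonious
  representation, and per-base splitting of multi-base substitutions,
  so call sets compare representation-independently.
* **Panel handling** — padded exon panels (exon ± 5 bp, merged),
  BED I/O, and footprint-overlap restriction of call sets.
* **Caller-threshold filtering** — the published screening-assay
  thresholds (min quality 10, min allele fraction 0.1, min coverage 10,
  homopolymer cap 9 bp, permissive strand settings) applied as a
  deterministic post-hoc filter with per-call rejection reasons.
* **Truth-set benchmarking** — allele-level TP/FP/FN with base-level TN
  accounting over the panel, giving analytical sensitivity
  `100·tp/(tp+fn)`, specificity `100·tn/(tn+fp)` and the Matthews
  correlation coefficient
  `(tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with false
  positives flagged by STR/homopolymer context.
* **Paired concordance** — per-pair `100·|A∩B|/|A∪B|` between DBS and VB
  call sets, with every discordant variant classified by direction,
  variant class, and coverage stratum (≤30× vs >30×, from the minimum of
  the pair's depths), plus cohort means and a high-coverage (>50×)
  summary table.
* **Coverage QC** — percent of panel bases at ≥50×, four tiers at
  cutoffs 90 / 97 / 99.5%, and cumulative run-level proportions.
* **Operations model** — schedule turnaround (4 days; 8 for repeats),
  weekly throughput (2 × 96 libraries/day → 1344 gross, 1302 net at a
  3/96 repeat rate), and itemized cost-per-sample aggregation with
  repeat inflation.
* **Synthetic cohorts** — seeded generation of reference contigs with
  embedded STR/poly-T tracts, ~50 kb panels, truth sets, 33 DBS/VB pairs
  with coverage-dependent injected errors, per-base depth tracks, and a
  ground-truth ledger that the comparison machinery must recover
  exactly.

## Worked example

Validation statistics from a confusion matrix (130 true positives, 10
false positives, no missed calls, 49,905 true-negative reference bases):

```r
library(nbsval)
cm <- confusion_matrix(tp = 130, fp = 10, fn = 0, tn = 49905)
sensitivity(cm)   # 100
specificity(cm)   # 99.98
mcc(cm)           # 0.9635
```

A full synthetic round trip — generate a study-scale cohort, benchmark
two samples against the truth set, and compare one DBS/VB pair:

```r
out <- simulate_cohort(list(seed = 7))
out$panel
#> <panel 'synthetic-panel'> 60 interval(s), 50,523 bases (padding 5 bp)

cms <- lapply(out$sim$samples[c("P01_DBS", "P01_VB")],
              compare_to_truth, truth = out$sim$truth, panel = out$panel)
validation_report(cms, ref = out$refinfo$ref,
                  str_regions = out$refinfo$str_regions)
#> Validation against truth set
#> <confusion> TP 95  FP 1  FN 1  TN 100,937
#>   sensitivity 98.96%  specificity 100.00%  MCC 0.990
#>   48 unique matching variant(s); 1 false positive(s)

compare_pair(out$sim$samples[["P01_DBS"]], out$sim$samples[["P01_VB"]],
             out$sim$depths[["P01_DBS"]], out$sim$depths[["P01_VB"]])
#> <paired_comparison A vs B> 96 calls, 47 concordant unique
#>   concordance all 95.9%, high-coverage 97.9%; 2 event(s)
```

Here the two samples of pair 1 each recovered 48 truth variants minus
one injected dropout; the one false positive and one missed call are
exactly the errors recorded in the generator's ledger
(`out$sim$ledger`), and discordance between the pair members sits in the
low-coverage stratum, so the high-coverage concordance is higher than
the all-regions figure.

The operations report at the reference configuration:

```r
ops_report()
#> Operations report
#>   turnaround: 4 day(s); repeat turnaround: 8 day(s)
#>   daily library capacity: 192; weekly throughput: 1344 gross / 1302 net unique
```

Config-driven runs (`run_validate()`, `run_concord()`,
`run_coverage_qc()`, `run_ops()`) take a YAML file — see
`inst/extdata/example_config.yaml` — and a thin CLI wrapper lives at
`inst/scripts/nbsval.R`.

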