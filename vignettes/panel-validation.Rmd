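---
title: "Analytical validation of targeted newborn-screening panels with nbsval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical validation of targeted newborn-screening panels with nbsval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsval)
```

## The problem

Newborn bloodspot screening laboratories that add targeted DNA sequencing
to their repertoire must demonstrate, before any clinical use, that the
assay calls variants correctly on its intended specimen. `nbsval`
implements the computational half of that demonstration for small
amplicon panels (tens of kilobases, a handful of genes): benchmarking
call sets against high-confidence truth sets, quantifying agreement
between paired dried-blood-spot (DBS) and venous-blood (VB) specimens
from the same individuals, tiering samples by coverage quality, and
working out what the workflow delivers operationally (turnaround,
weekly throughput, cost per sample).

Everything downstream of read alignment and variant calling is in scope.
The caller itself is not re-implemented: its published filter thresholds
are applied as a deterministic post-hoc stage, so the package can audit
a call set against the thresholds without access to the instrument
software.

## Variant representation

All comparisons are allele-level set operations on the key
(contig, position, ref, alt), which is only meaningful after every
record has been reduced to a canonical form:

1. **Decomposition.** Multi-allelic records are split into one biallelic
   record per alternate allele. The genotype of each output reflects
   only its own allele: present on both haplotypes = `hom`, on one =
   `het`, undetermined = `unknown`.
2. **Left-align and trim.** Each biallelic record is normalized by
   repeatedly truncating a shared rightmost base (extending one base
   leftward from the reference when an allele would empty) and then
   truncating shared leftmost bases while both alleles keep at least one
   base. The result is the unique leftmost, parsimonious representation;
   the operation is idempotent, and applying the normalized record to
   the reference reproduces exactly the same edited sequence as the
   input. A normalization that would walk past position 1 of a contig
   raises an error rather than emitting half-shifted coordinates.
3. **Substitution splitting.** Equal-length multi-base substitutions are
   split into their per-base SNVs (identical bases dropped). Truth sets
   in this setting are overwhelmingly SNVs, and per-base splitting makes
   matching independent of how an upstream caller chose to block
   substitutions.

Coordinates are 1-based inclusive in variant records (the VCF
convention) and 0-based half-open in intervals (the BED convention);
conversion happens only at I/O and footprint boundaries. This split is
deliberate — one consistent convention per data type, with no ad hoc
arithmetic elsewhere.

## Panel construction and restriction

A panel is built from exon intervals expanded by a padding (default 5 bp)
on each side, clamped at zero and merged; 3′UTR targets are supplied
simply as extra intervals. The merged size is the panel's base count and
the denominator of all base-level statistics. A call is *in panel* when
any base of its reference footprint overlaps a panel base — the same
semantics as a BED intersection — so a deletion anchored just outside
the panel but reaching into it is retained.

## Truth-set benchmarking

`compare_to_truth()` scores a normalized, panel-restricted query call
set against a truth set:

* **TP/FP/FN** are allele-level set intersections and differences.
  Genotype is deliberately not part of the match key: zygosity
  mismatches are annotated separately rather than double-counted as an
  FP plus an FN (a config switch enables genotype-aware matching).
* **TN** is counted at base level: every panel position not covered by
  the footprint of any TP/FP/FN event counts once as a correctly
  reported reference base. When all events occupy distinct single
  positions, `tp + fp + fn + tn` equals the panel size exactly — an
  invariant the test-suite asserts. Indel footprints consume every
  reference position they span.

From the confusion matrix: sensitivity `100·tp/(tp+fn)`, specificity
`100·tn/(tn+fp)` and the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{tp\cdot tn - fp\cdot fn}
{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}},$$

with the convention that a zero denominator factor yields 0. On the kind
of counts this design produces (tens of true positives against ~50,000
true negatives), MCC is the statistic that actually discriminates:
specificity is pinned near 100% by the enormous TN count regardless of
how many false positives occur.

False positives are additionally flagged by context — inside a declared
short-tandem-repeat interval, or inside a homopolymer run of ≥5 bases —
because repetitive tracts are exactly where alignment and flow-space
artifacts concentrate and where a laboratory may pre-register exclusion
rules.

```{r}
cm <- confusion_matrix(tp = 130, fp = 10, fn = 0, tn = 49905)
c(sensitivity = sensitivity(cm), specificity = specificity(cm), mcc = mcc(cm))
```

## Paired-specimen concordance

`compare_pair()` formalizes "percentage of variants matching" between a
DBS and a VB call set from the same individual as
$100\cdot|A\cap B|/|A\cup B|$ — the union denominator is symmetric in
the two members and counts every discordant variant exactly once. A
`mean_size` denominator ($2|A\cap B|/(|A|+|B|)$) is available as a
config switch for sensitivity analysis.

Every variant in the symmetric difference becomes one discordance event,
classified by direction (`only_in_A`/`only_in_B`), variant class
(SNV/indel) and coverage stratum. The stratum is derived from the
*minimum* of the two samples' depths at the variant position, against a
threshold of 30× by default: a variant is only reliably assessable when
both specimens clear the floor, so the pair is judged by its weaker
member. Cohort summaries report the mean per-pair concordance over all
regions and over the high stratum, plus a two-column table that
recomputes the restricted figure at a stricter floor (50× by default).

## Coverage QC

Per-sample QC is the percentage of panel bases with depth at or above a
floor (50×, inclusive), classified into four tiers at cutoffs 0.90, 0.97
and 0.995: below 90% a sample has failed; 90–97% may have substantial
gaps; 97–99.5% minor gaps; at or above 99.5% the sample is unlikely to
have meaningful gaps. A sample exactly at a cutoff belongs to the better
tier (≥ semantics, consistent with "below the cutoff = failed").
Run-level summaries report, for each cutoff, the cumulative proportion
of samples at or above it — cumulative rather than exclusive, because
that is the operationally meaningful "fraction of the run usable at this
stringency". Depth tables are read in the long per-base format produced
by standard depth tools (chrom, 0-based position, depth, sample);
positions absent from a track count as depth 0.

## The operations model

The laboratory model is deliberately plain arithmetic, because that is
all the inputs support:

* Turnaround is the day-span of an ordered stage schedule; the default
  four-day schedule runs booking-on/punching/extraction/library-start,
  digestion/barcoding/QC/pooling/chip-loading, sequencing/processing,
  analysis/reporting. A repeat-tested sample runs two full sequential
  cycles: eight days.
* Weekly throughput is `samples_per_run × runs_per_day × days_per_week ×
  sequencers` gross slots (96 × 2 × 7 × 1 = 1344), of which a fraction
  `repeat_rate` (3/96 by default) is consumed by repeats: 1302 net
  unique samples.
* Cost per sample is the sum of user-supplied itemized components, with
  repeat-sensitive items inflated by `1/(1 − repeat_rate)`. Published
  aggregate costs cannot be decomposed into components, so the package
  ships only a clearly-marked synthetic itemization in its example
  config and guarantees the aggregation arithmetic, nothing more.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the study conditions: five gene contigs
of twelve exons each, padded by 5 bp into a ~50 kb merged panel (the
generator contracts to land within 5% of the target); a truth set of 46
SNVs and 2 three-base deletions placed at positions whose homopolymer
run is ≤5; an embedded (CA)₁₂ short-tandem-repeat tract and poly-T
tracts of 8 and 10 bases inside exons (the 8-mer is the false-positive
indel site — long enough to be artifact-prone, short enough to survive
the 9 bp homopolymer cap; the 10-mer exists to exercise the cap); and 33
DBS/VB pairs, 66 samples.

Depth is modelled per 150 bp amplicon-surrogate window as negative
binomial (dispersion 8) with mean 200× in the normal regime and 20× in
the systematically-low regime (4% of windows). Low-regime depths are
clamped to 10–30× and normal-regime depths floored at 35×. The clamps
are a design choice, not a convenience: they make stratum membership
deterministic, so that "errors confined to the ≤30× stratum imply
exactly 100% high-coverage concordance" is a provable property of the
generated data rather than a statistical tendency, and low-regime calls
still clear the caller's 10× minimum-coverage filter so that filtering
is a no-op on generated call sets and ledger recovery is exact through
the full pipeline.

Errors are injected per sample: each truth variant is dropped with
probability 0.4 in low-coverage windows and 0.005 elsewhere
(false negatives); false-positive SNVs arrive at a Poisson rate of 0.12
per sample at allele fraction 0.15, placed in low-coverage windows with
probability 0.75; false-positive poly-T indels arrive at rate 0.15 in
DBS libraries and 0 in VB — the artifact class is characteristic of the
dried-blood-spot libraries. False-positive positions are unique within a
pair, which is what lets the ledger predict pairwise discordance by set
algebra with no collision cases. Event strata in the ledger are computed
from the *emitted* depth tracks, so the ledger describes the files
exactly, byte for byte, rerun for rerun (a seeded generation writes
byte-identical output; the VCF writer embeds no timestamps for this
reason).

What the generator does **not** emulate: read-level error processes
(flow-space signal, strand bias — the strand fields are populated but
neutral), systematic GC or amplicon dropout beyond the binary regime
labels, population allele-frequency structure (every individual shares
one truth set, the replicate design of a cell-line validation), CNVs and
structural variants, and contamination. Passing the recovery tests
therefore demonstrates that the *accounting machinery* is exact —
that injected signal is recovered without loss or double counting — not
that the error model predicts real DBS behaviour.

## Numerical and degenerate-input choices

* Statistics with empty denominators (`tp+fn = 0`, `tn+fp = 0`, empty
  panels, empty schedules, empty cohorts) raise typed errors rather than
  returning NA; the MCC zero-factor case returns 0 by documented
  convention.
* Tier assignment adds a 10⁻⁹ tolerance before comparing a sample's
  percentage to a cutoff, so that count ratios which are exactly a
  cutoff in rational arithmetic are not pushed down a tier by binary
  floating-point representation.
* `compare_to_truth()` and `compare_pair()` refuse input containing
  records whose alleles share a trailing base, share a leading base at
  length ≥2, or form an untrimmed multi-base substitution — the
  reference-free signature of unnormalized data. (Full re-normalization
  needs the reference, which these operations deliberately do not take.)
* The caller-threshold filter evaluates the homopolymer cap at the first
  alt-affected reference base: the call position for SNVs, the base
  after the anchor for indels. Rejections report the first failing
  criterion in the fixed order qual, allele fraction, depth, strand
  depth, strand bias, homopolymer. Missing annotations never fail a
  threshold. At the default strand settings (max bias 1, p-value 0) the
  strand-bias stage is a documented no-op, retained for config fidelity.
* Filtering precedes panel restriction by default (caller-then-intersect
  order); a config flag swaps the order for sensitivity analysis.

## Problem sizes

The test-suite exercises the normalizer against an exhaustive
apply-and-compare oracle on 1,000 random contigs of up to 60 bp, and the
recovery properties on a full-scale cohort (~50 kb panel, 33 pairs, 66
samples) plus scaled-down cohorts (~1.7 kb, 3 pairs) for structural
checks. The QC construction is exercised at its natural size of 288
samples. These sizes keep the whole suite to a few minutes on a single
CPU while covering the study-scale configuration end to end.

## Known limitations

* Allele-level matching cannot express haplotype-aware equivalence of
  complex nearby variants; a truth set representing a cluster
  differently from the query (beyond what normalization resolves) will
  score spurious FP+FN pairs.
* Base-level TN accounting pools positions per sample; cross-sample
  totals are sums of per-sample matrices, which is a convention, not an
  inevitability.
* The concordance denominator is undefined for a pair with no variants
  at all (reported as NA and excluded from cohort means).
* The ops model is static arithmetic: no queueing, no failure cascades,
  no staffing constraints.
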