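# Example pipeline configuration. Paths are resolved relative to this
# file's directory; point them at a simulated cohort (see
# nbsval::simulate_cohort) or at your own exported files.

reference: reference.fasta
panel_bed: panel.bed
str_bed: str_regions.bed
truth_vcf: truth.vcf
out_dir: nbsval_out

samples:
  P01_DBS:
    vcf: P01_DBS.vcf
    depth: P01_DBS.depth.tsv
  P01_VB:
    vcf: P01_VB.vcf
    depth: P01_VB.depth.tsv

pairs:
  - [P01_DBS, P01_VB]

# caller thresholds applied as a post-hoc filter (defaults shown)
thresholds:
  min_qual: 10
  min_allele_fraction: 0.1
  min_depth: 10
  min_depth_each_strand: 0
  max_strand_bias: 1
  strand_bias_pvalue: 0
  max_homopolymer_len: 9

concordance:
  coverage_threshold: 30
  high_coverage_threshold: 50

qc:
  depth_threshold: 50
  tier_cutoffs: [0.90, 0.97, 0.995]

ops:
  samples_per_run: 96
  runs_per_day: 2
  days_per_week: 7
  repeat_rate: 0.03125   # 3/96
  sequencers: 1

# placeholder itemization, synthetic and non-authoritative: real
# per-sample component costs are laboratory-specific and must be
# supplied by the user; only the aggregation arithmetic is guaranteed
costs:
  items:
    consumables: 55.00
    equipment: 4.00
    labour: 2.00
  repeat_sensitive: [consumables]
  labour_items: [labour]
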