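# scaled-down generator configuration used for fast structural tests;
# cohort-scale behaviour is exercised in the acceptance suite
small_cfg <- function(seed = 101, ...) {
  sim_config(seed = seed, n_genes = 2L, exons_per_gene = 4L,
             exon_len_mean = 200, exon_len_sd = 30, intron_len = 120L,
             target_panel_bases = 1700L, n_truth_snvs = 12L,
             n_truth_indels = 1L, n_pairs = 3L, ...)
}

test_that("reference generation is deterministic and embeds the tracts", {
  cfg <- small_cfg()
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(unclass(r1$ref), unclass(r2$ref))

  runs <- homopolymer_runs(r1$ref, min_len = 8L)
  t_runs <- runs[runs$base == "T", ]
  expect_true(any(t_runs$length == 8L))
  expect_true(any(t_runs$length == 10L))   # requested poly-T lengths

  # the declared STR interval really holds the repeat unit
  str <- r1$str_regions
  tract <- ref_base(r1$ref, str$contig, str$start + 1L, str$end - str$start)
  expect_equal(tract, strrep("CA", 12))
})

test_that("generated panels respect the scale contract", {
  cfg <- small_cfg()
  refinfo <- make_reference(cfg)
  panel <- build_panel(refinfo$exons, padding_bp = cfg$panel_padding)
  expect_lt(abs(panel_total_bases(panel) - cfg$target_panel_bases) /
              cfg$target_panel_bases, 0.05)
})

test_that("base composition of generated contigs is near-uniform", {
  cfg <- sim_config(seed = 5, n_genes = 5L, exons_per_gene = 10L,
                    exon_len_mean = 500)
  refinfo <- make_reference(cfg)
  s <- paste(unclass(refinfo$ref), collapse = "")
  gc <- (nchar(gsub("[^GC]", "", s))) / nchar(s)
  expect_lt(abs(gc - 0.5), 0.05)
})

test_that("the ledger exactly describes the in-memory call sets", {
  cfg <- small_cfg()
  refinfo <- make_reference(cfg)
  panel <- build_panel(refinfo$exons, padding_bp = cfg$panel_padding)
  sim <- make_truth_and_calls(cfg, refinfo, panel)
  for (sid in names(sim$samples)) {
    led <- sim$ledger$samples[[sid]]
    cm <- compare_to_truth(sim$samples[[sid]], sim$truth, panel)
    expect_equal(cm$fn, length(led$fn))
    expect_equal(cm$fp, length(led$fp))
    expect_setequal(variant_key(attr(cm, "fn_calls")), led$fn)
    expect_setequal(variant_key(attr(cm, "fp_calls")), led$fp)
  }
})

test_that("emitted files reproduce the ledger after re-reading (round trip)", {
  cfg <- small_cfg(seed = 77)
  refinfo <- make_reference(cfg)
  panel <- build_panel(refinfo$exons, padding_bp = cfg$panel_padding)
  sim <- make_truth_and_calls(cfg, refinfo, panel)
  dir <- withr::local_tempdir()
  write_cohort(sim, refinfo, panel, dir)

  ref <- read_fasta(file.path(dir, "reference.fasta"))
  panel_back <- build_panel(read_bed(file.path(dir, "panel.bed")),
                            padding_bp = 0)
  expect_equal(panel_total_bases(panel_back), panel_total_bases(panel))
  truth <- read_calls(file.path(dir, "truth.vcf"), ref)
  expect_setequal(variant_key(truth), sim$ledger$truth_keys)

  for (sid in names(sim$samples)) {
    # written FPs are denormalized on purpose; reading through the
    # normalizer must recover the ledgered keys exactly
    calls <- restrict_calls(read_calls(file.path(dir, paste0(sid, ".vcf")),
                                       ref), panel_back)
    cm <- compare_to_truth(calls, truth, panel_back)
    expect_setequal(variant_key(attr(cm, "fp_calls")),
                    sim$ledger$samples[[sid]]$fp)
    expect_setequal(variant_key(attr(cm, "fn_calls")),
                    sim$ledger$samples[[sid]]$fn)
  }
})

test_that("cohort emission is byte-identical across reruns", {
  cfg <- small_cfg(seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    refinfo <- make_reference(cfg)
    panel <- build_panel(refinfo$exons, padding_bp = cfg$panel_padding)
    sim <- make_truth_and_calls(cfg, refinfo, panel)
    write_cohort(sim, refinfo, panel, d)
  }
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(h1), unname(h2))
})

test_that("error-free configurations give perfect downstream agreement", {
  cfg <- small_cfg(seed = 8, p_fn_low = 0, p_fn_high = 0, fp_snv_rate = 0,
                   fp_indel_polyt_rate = 0)
  refinfo <- make_reference(cfg)
  panel <- build_panel(refinfo$exons, padding_bp = cfg$panel_padding)
  sim <- make_truth_and_calls(cfg, refinfo, panel)
  for (sid in names(sim$samples)) {
    expect_equal(variant_key(sim$samples[[sid]]), variant_key(sim$truth))
  }
  pr <- compare_pair(sim$samples[[1]], sim$samples[[2]],
                     sim$depths[[1]], sim$depths[[2]])
  expect_equal(pr$concordance_all_pct, 100)
})

test_that("impossible variant demands raise a capacity error", {
  cfg <- small_cfg()
  cfg$n_truth_snvs <- 100000L
  refinfo <- make_reference(cfg)
  panel <- build_panel(refinfo$exons, padding_bp = cfg$panel_padding)
  expect_error(make_truth_and_calls(cfg, refinfo, panel),
               class = "nbsval_capacity")
})

test_that("QC cohorts are constructed with the prescribed tier membership", {
  qc <- make_qc_cohort(n_samples = 10L, cumulative_counts = c(4L, 7L, 9L),
                       panel_bases = 400L, seed = 3)
  qcs <- lapply(qc$tracks, sample_qc, panel = qc$panel)
  rs <- run_summary(qcs)
  expect_equal(rs$cumulative$n_at_or_above, c(9, 7, 4))
  expect_equal(vapply(qcs, `[[`, character(1), "tier"), qc$expected_tiers)

  all_pass <- make_qc_cohort(n_samples = 5L,
                             cumulative_counts = c(5L, 5L, 5L),
                             panel_bases = 400L, seed = 4)
  rs2 <- run_summary(lapply(all_pass$tracks, sample_qc, panel = all_pass$panel))
  expect_equal(rs2$cumulative$proportion_pct, c(100, 100, 100))

  expect_error(make_qc_cohort(n_samples = 0L), class = "nbsval_bad_config")
  expect_error(make_qc_cohort(n_samples = 4L,
                              cumulative_counts = c(5L, 4L, 3L)),
               class = "nbsval_bad_config")
})
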