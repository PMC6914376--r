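mk_track <- function(depths, contig = "qc", id = "s1") {
  coverage_track(contig, seq_along(depths) - 1L, depths, sample_id = id)
}

test_that("percent bases at depth and tier assignment follow the cutoffs", {
  panel <- build_panel(genomic_intervals("qc", 0L, 1000L), padding_bp = 0)
  d <- rep(10L, 1000); d[1:995] <- 60L
  q <- sample_qc(mk_track(d), panel)
  expect_equal(q$pct_bases_at_depth, 99.5)
  expect_equal(q$tier, "pass_clean")   # boundary belongs to the better tier

  d2 <- rep(10L, 1000); d2[1:899] <- 60L
  q2 <- sample_qc(mk_track(d2), panel)
  expect_equal(q2$pct_bases_at_depth, 89.9)
  expect_equal(q2$tier, "fail")

  q3 <- sample_qc(mk_track(rep(0L, 1000)), panel)
  expect_equal(q3$pct_bases_at_depth, 0)
  expect_equal(q3$tier, "fail")

  # depth exactly at the floor counts (>= semantics)
  d4 <- rep(50L, 1000)
  expect_equal(sample_qc(mk_track(d4), panel)$pct_bases_at_depth, 100)
})

test_that("positions absent from the track count as depth zero", {
  panel <- build_panel(genomic_intervals("qc", 0L, 100L), padding_bp = 0)
  half <- coverage_track("qc", 0:49, rep(60L, 50))
  expect_equal(sample_qc(half, panel)$pct_bases_at_depth, 50)
  expect_error(sample_qc(half, build_panel(genomic_intervals("x", 0, 1),
                                           padding_bp = 0)[0, ]),
               class = "nbsval_bad_config")
})

test_that("sample_qc is invariant to interval order and splitting", {
  set.seed(31)
  d <- sample(0:120, 300, replace = TRUE)
  track <- mk_track(d)
  whole <- build_panel(genomic_intervals("qc", 0L, 300L), padding_bp = 0)
  split2 <- build_panel(genomic_intervals("qc", c(150L, 0L), c(300L, 150L)),
                        padding_bp = 0)
  expect_equal(sample_qc(track, split2)$pct_bases_at_depth,
               sample_qc(track, whole)$pct_bases_at_depth)
})

test_that("pct bases at depth agrees with the per-position brute force", {
  set.seed(17)
  for (rep in 1:5) {
    n_iv <- sample(2:4, 1)
    st <- sort(sample(seq(0, 160, by = 40), n_iv))
    panel <- build_panel(genomic_intervals("qc", st, st + sample(10:30, n_iv)),
                         padding_bp = 0)
    track <- mk_track(sample(0:80, 200, replace = TRUE))
    got <- sample_qc(track, panel, qc_policy(depth_threshold = 40))
    expect_equal(got$pct_bases_at_depth,
                 brute_force_pct_at_depth(track, panel, 40))
  }
})

test_that("region mean coverage averages per-base depths", {
  track <- mk_track(c(rep(20L, 5), rep(40L, 5)))
  expect_equal(region_mean_coverage(track, genomic_intervals("qc", 0, 10)), 30)
  expect_equal(region_mean_coverage(track, genomic_intervals("qc", 0, 5)), 20)
  expect_error(region_mean_coverage(track, data.frame(contig = "qc",
                                                      start = 5, end = 5)),
               class = "nbsval_bad_interval")
})

test_that("run summary reports cumulative proportions and tier counts", {
  panel <- build_panel(genomic_intervals("qc", 0L, 1000L), padding_bp = 0)
  mk <- function(pct) {
    d <- rep(10L, 1000); if (pct > 0) d[seq_len(pct * 10)] <- 60L
    sample_qc(mk_track(d), panel)
  }
  samples <- lapply(c(100, 99.6, 99.5, 98, 95, 80), mk)
  rs <- run_summary(samples)
  expect_equal(rs$cumulative$n_at_or_above, c(5, 4, 3))
  # cumulative proportions are monotone non-increasing in the cutoff
  expect_true(all(diff(rs$cumulative$n_at_or_above) <= 0))
  expect_equal(unname(rs$tier_counts[c("fail", "may_have_gaps",
                                       "minor_gaps", "pass_clean")]),
               c(1L, 1L, 1L, 3L), ignore_attr = TRUE)
  expect_error(run_summary(list()), class = "nbsval_bad_config")

  all_full <- run_summary(lapply(c(100, 100), mk))
  expect_equal(all_full$cumulative$proportion_pct, c(100, 100, 100))
})

test_that("depth tables round-trip through TSV", {
  track <- mk_track(sample(0:50, 40), id = "S7")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_tsv(track, path)
  back <- read_depth_tsv(path)
  expect_equal(back$contig, track$contig)
  expect_equal(back$pos, track$pos)
  expect_equal(back$depth, track$depth)
  expect_equal(attr(back, "sample_id"), "S7")
})
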