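ref_flat <- ref_seqs(c(c1 = paste(rep("ACGT", 30), collapse = "")))

mk_call <- function(qual = 50, af = 0.5, dp = 100L, fwd = 50L, rev = 50L,
                    sb = 0.5, pos = 10L, contig = "c1", ref = NULL,
                    alt = NULL) {
  refb <- ref_base(ref_flat, contig, pos)
  variant_records(contig, pos, ref %||% refb,
                  alt %||% setdiff(c("A", "C", "G", "T"), refb)[1],
                  qual = qual, allele_fraction = af, depth = dp,
                  depth_fwd = fwd, depth_rev = rev, strand_bias = sb)
}

test_that("each threshold rejects with its reason code, in evaluation order", {
  t <- filter_thresholds()
  cases <- list(
    list(call = mk_call(qual = 9.9, af = 0.5, dp = 100), reason = "qual"),
    list(call = mk_call(qual = 50, af = 0.09, dp = 100),
         reason = "allele_fraction"),
    list(call = mk_call(dp = 9L, fwd = 4L, rev = 5L), reason = "depth"),
    list(call = mk_call(), reason = NA)
  )
  for (cs in cases) {
    out <- filter_calls(cs$call, t, ref_flat)
    if (is.na(cs$reason)) {
      expect_equal(nrow(out$passed), 1L)
    } else {
      expect_equal(out$rejected$reason, cs$reason)
    }
  }
  # evaluation order: a call failing everything reports the first criterion
  worst <- mk_call(qual = 1, af = 0.01, dp = 1L, fwd = 0L, rev = 1L)
  expect_equal(filter_calls(worst, t, ref_flat)$rejected$reason, "qual")
})

test_that("per-strand depth threshold applies to each strand", {
  t <- filter_thresholds(min_depth_each_strand = 5L)
  bad <- mk_call(dp = 100L, fwd = 96L, rev = 4L)
  good <- mk_call(dp = 100L, fwd = 50L, rev = 50L)
  expect_equal(filter_calls(bad, t, ref_flat)$rejected$reason, "strand_depth")
  expect_equal(nrow(filter_calls(good, t, ref_flat)$passed), 1L)
})

test_that("homopolymer cap rejects calls in long runs", {
  ref <- ref_seqs(c(h = paste0("GG", strrep("T", 10), "ACGTACGTAC")))
  snv_in_run <- variant_records("h", 6, "T", "A", qual = 50,
                                allele_fraction = 0.5, depth = 100,
                                depth_fwd = 50, depth_rev = 50)
  out <- filter_calls(snv_in_run, filter_thresholds(), ref)
  expect_equal(out$rejected$reason, "homopolymer")

  # an insertion anchored just before the run is judged by the run itself
  ins <- variant_records("h", 2, "G", "GT", qual = 50,
                         allele_fraction = 0.5, depth = 100,
                         depth_fwd = 50, depth_rev = 50)
  out2 <- filter_calls(ins, filter_thresholds(), ref)
  expect_equal(out2$rejected$reason, "homopolymer")
  # the same insertion passes when the cap only applies to SNVs
  out3 <- filter_calls(ins, filter_thresholds(homopolymer_applies = "SNV"),
                       ref)
  expect_equal(nrow(out3$passed), 1L)
})

test_that("filter partitions candidates and preserves order", {
  set.seed(5)
  pos <- sample(100, 30)
  calls <- do.call(rbind, lapply(1:30, function(i) {
    mk_call(qual = sample(c(5, 50), 1), af = sample(c(0.05, 0.5), 1),
            pos = pos[i])
  }))
  out <- filter_calls(calls, filter_thresholds(), ref_flat)
  expect_equal(nrow(out$passed) + nrow(out$rejected), nrow(calls))
  expect_equal(length(intersect(rownames(out$passed), rownames(out$rejected))),
               0L)
  # order preserved within each partition
  all_keys <- variant_key(calls)
  expect_equal(variant_key(out$passed),
               all_keys[all_keys %in% variant_key(out$passed)])
})

test_that("relaxing a threshold never shrinks the passed set", {
  set.seed(6)
  pos <- sample(100, 40)
  calls <- do.call(rbind, lapply(1:40, function(i) {
    mk_call(qual = runif(1, 0, 30), af = runif(1, 0, 0.4),
            dp = sample(5:120, 1), pos = pos[i])
  }))
  strict <- filter_calls(calls, filter_thresholds(), ref_flat)
  for (relax in list(filter_thresholds(min_qual = 0),
                     filter_thresholds(min_allele_fraction = 0),
                     filter_thresholds(min_depth = 0))) {
    loose <- filter_calls(calls, relax, ref_flat)
    expect_true(all(variant_key(strict$passed) %in%
                      variant_key(loose$passed)))
  }
  # fully permissive thresholds pass everything
  open <- filter_thresholds(min_qual = 0, min_allele_fraction = 0,
                            min_depth = 0, min_depth_each_strand = 0,
                            max_strand_bias = 1,
                            max_homopolymer_len = .Machine$integer.max)
  expect_equal(nrow(filter_calls(calls, open, ref_flat)$passed), nrow(calls))
})
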