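mk_panel <- function(bases = 100L) {
  build_panel(genomic_intervals("c", 0L, bases), padding_bp = 0)
}

test_that("confusion counts follow the base-level accounting definition", {
  panel <- mk_panel(100)
  truth <- variant_records("c", c(10, 20), c("A", "C"), c("G", "T"))
  query <- variant_records("c", c(10, 20, 30), c("A", "C", "G"),
                           c("G", "T", "A"))
  cm <- compare_to_truth(query, truth, panel)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2, 1, 0, 97))

  empty <- empty_variants()
  cm0 <- compare_to_truth(empty, empty, mk_panel(50))
  expect_equal(c(cm0$tp, cm0$fp, cm0$fn, cm0$tn), c(0, 0, 0, 50))

  # same-position allele mismatch: one FP, one FN, one position consumed
  cm1 <- compare_to_truth(variant_records("c", 10, "A", "T"),
                          variant_records("c", 10, "A", "G"), panel)
  expect_equal(c(cm1$tp, cm1$fp, cm1$fn, cm1$tn), c(0, 1, 1, 99))
})

test_that("conservation holds on single-position fixtures and swaps are symmetric", {
  set.seed(21)
  panel <- mk_panel(200)
  for (rep in 1:10) {
    pos <- sample(1:200, 12)
    refs <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    alts <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                   character(1))
    truth <- variant_records("c", pos[1:8], refs[1:8], alts[1:8])
    query <- variant_records("c", pos[3:12], refs[3:12], alts[3:12])
    cm <- compare_to_truth(query, truth, panel)
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, panel_total_bases(panel))
    sw <- compare_to_truth(truth, query, panel)
    expect_equal(sw$fp, cm$fn)
    expect_equal(sw$fn, cm$fp)
    expect_equal(sw$tp, cm$tp)
    expect_equal(sw$tn, cm$tn)
  }
})

test_that("comparison is representation-independent after normalization", {
  s <- "GGGCACACACTAAGGT"
  ref <- ref_seqs(c(c = s))
  panel <- mk_panel(nchar(s))
  # the same deletion in two different unnormalized representations
  a <- variant_records("c", 4, "CACA", "CA")
  b <- variant_records("c", 6, "CAC", "C")
  expect_equal(apply_edit(s, 4, "CACA", "CA"), apply_edit(s, 6, "CAC", "C"))
  na <- normalize_calls(a, ref)
  nb <- normalize_calls(b, ref)
  cm <- compare_to_truth(na, nb, panel)
  expect_equal(cm$tp, 1)
  expect_equal(cm$fp + cm$fn, 0)
  # unnormalized input is refused
  expect_error(compare_to_truth(a, nb, panel), class = "nbsval_precondition")
})

test_that("sensitivity, specificity and MCC follow their formulas", {
  expect_equal(sensitivity(confusion_matrix(130, 0, 0, 1)), 100)
  expect_equal(sensitivity(confusion_matrix(1, 0, 1, 0)), 50)
  expect_equal(sensitivity(confusion_matrix(0, 0, 5, 0)), 0)
  expect_error(sensitivity(confusion_matrix(0, 1, 0, 1)),
               class = "nbsval_undefined")

  expect_equal(specificity(confusion_matrix(0, 10, 0, 90)), 90)
  expect_error(specificity(confusion_matrix(1, 0, 1, 0)),
               class = "nbsval_undefined")

  expect_equal(mcc(confusion_matrix(10, 0, 0, 90)), 1)
  expect_equal(mcc(confusion_matrix(1, 1, 1, 1)), 0)
  expect_equal(mcc(confusion_matrix(0, 1, 1, 0)), -1)
  # zero denominator factor convention
  expect_equal(mcc(confusion_matrix(0, 0, 3, 7)), 0)
})

test_that("mcc stays in [-1, 1] and hits 1 only for perfect classification", {
  set.seed(3)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:500, 1))
    m <- mcc(cm)
    expect_gte(m, -1); expect_lte(m, 1)
    if (cm$fp == 0 && cm$fn == 0 && cm$tp > 0 && cm$tn > 0) {
      expect_equal(m, 1)
    }
  }
})

test_that("false positives are flagged by repeat context", {
  ref <- ref_seqs(c(c = paste0("ACGTA", strrep("CA", 6), strrep("T", 6), "GCGT")))
  strs <- genomic_intervals("c", 5, 17)    # the CA tract
  fp <- variant_records("c", c(7, 20, 2), c("A", "T", "C"), c("T", "C", "G"))
  out <- flag_context(fp, ref, strs)
  expect_equal(out$in_STR, c(TRUE, FALSE, FALSE))
  expect_equal(out$in_homopolymer, c(FALSE, TRUE, FALSE))
})

test_that("pooled validation reports count unique matching variants once", {
  panel <- mk_panel(100)
  truth <- variant_records("c", c(10, 20), c("A", "C"), c("G", "T"))
  q1 <- truth
  q2 <- rbind(truth, variant_records("c", 30, "G", "A"))
  cms <- list(s1 = compare_to_truth(q1, truth, panel),
              s2 = compare_to_truth(q2, truth, panel))
  rep <- validation_report(cms)
  expect_equal(rep$confusion$tp, 4)
  expect_equal(rep$confusion$fp, 1)
  expect_equal(rep$unique_matching_variants, 2)
  expect_equal(rep$sensitivity, 100)
  expect_equal(nrow(rep$fp_breakdown), 1)
})
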