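test_that("multi-allelic calls decompose into per-allele biallelic records", {
  raw <- data.frame(contig = "c", pos = 100L, ref = "A", alt = "G,T",
                    gt = "1/2", stringsAsFactors = FALSE)
  out <- decompose(raw)
  expect_equal(out$alt, c("G", "T"))
  expect_equal(out$pos, c(100L, 100L))
  expect_equal(out$genotype, c("het", "het"))

  hom <- decompose(data.frame(contig = "c", pos = 100L, ref = "A",
                              alt = "G", gt = "1/1"))
  expect_equal(hom$genotype, "hom")

  # alts are carried through unchanged; normalization is a separate step
  mixed <- decompose(data.frame(contig = "c", pos = 50L, ref = "AC",
                                alt = "GC,A", gt = "1/2"))
  expect_equal(mixed$ref, c("AC", "AC"))
  expect_equal(mixed$alt, c("GC", "A"))
  expect_equal(mixed$genotype, c("het", "het"))

  # allele multiset preserved under decomposition
  expect_setequal(out$alt, c("G", "T"))
})

test_that("decompose assigns het/hom/unknown from genotype indices", {
  gt_cases <- list(list(gt = "0/1", want = "het"),
                   list(gt = "1|1", want = "hom"),
                   list(gt = "./.", want = "unknown"),
                   list(gt = "0/0", want = "unknown"))
  for (cs in gt_cases) {
    out <- decompose(data.frame(contig = "c", pos = 10L, ref = "A",
                                alt = "G", gt = cs$gt))
    expect_equal(out$genotype, cs$want, info = cs$gt)
  }
  expect_error(
    decompose(data.frame(contig = "c", pos = 10L, ref = "A", alt = "G",
                         gt = "1/2")),
    class = "nbsval_malformed")
})

test_that("normalization matches frozen exhaustive-oracle results", {
  # SNVs are fixed points
  ref <- ref_seqs(c(c1 = "ACGTACGT"))
  nv <- normalize_variant("c1", 3, "G", "T", ref)
  expect_equal(nv, list(pos = 3L, ref = "G", alt = "T"))

  # frozen from the enumerate/apply oracle over the full contig
  ref2 <- ref_seqs(c(c1 = "GGGCACACACT"))
  expect_equal(normalize_variant("c1", 4, "CACA", "CA", ref2),
               list(pos = 3L, ref = "GCA", alt = "G"))
  ref3 <- ref_seqs(c(c1 = "GTTTTTTC"))
  expect_equal(normalize_variant("c1", 7, "T", "TT", ref3),
               list(pos = 1L, ref = "G", alt = "GT"))
})

test_that("normalization errors are explicit", {
  ref <- ref_seqs(c(c1 = "TTTTAC"))
  # an insertion in a run reaching the contig start cannot left-extend
  expect_error(normalize_variant("c1", 2, "T", "TT", ref),
               class = "nbsval_left_extend")
  expect_error(normalize_variant("c1", 2, "G", "A", ref),
               class = "nbsval_ref_mismatch")
})

test_that("normalize is idempotent and equivalence-preserving on random cases", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_contig(sample(20:60, 1))
    cs <- random_edit_case(s)
    ref <- ref_seqs(c(ctg = s))
    nv <- tryCatch(
      normalize_variant("ctg", cs$pos, cs$ref, cs$alt, ref),
      nbsval_left_extend = function(e) NULL)
    if (is.null(nv)) next
    # applying the normalized representation reproduces the same edit
    expect_equal(apply_edit(s, nv$pos, nv$ref, nv$alt), cs$edited)
    # idempotence
    nv2 <- normalize_variant("ctg", nv$pos, nv$ref, nv$alt, ref)
    expect_equal(nv2, nv)
  }
})

test_that("normalize_calls splits equal-length substitutions into SNVs", {
  ref <- ref_seqs(c(c1 = "AACAGTT"))
  v <- variant_records("c1", 3, "CAG", "GAT")
  out <- normalize_calls(v, ref)
  expect_equal(nrow(out), 2L)
  expect_equal(out$pos, c(3L, 5L))
  expect_equal(out$ref, c("C", "G"))
  expect_equal(out$alt, c("G", "T"))
  expect_true(all(variant_class(out) == "SNV"))
  # applying all split records jointly reproduces the original edit
  s <- "AACAGTT"
  for (i in rev(seq_len(nrow(out)))) {
    s <- apply_edit(s, out$pos[i], out$ref[i], out$alt[i])
  }
  expect_equal(s, apply_edit("AACAGTT", 3, "CAG", "GAT"))
})

test_that("homopolymer length counts the maximal run containing a position", {
  ref <- ref_seqs(c(c1 = "GTTTTTTC", c2 = "ACGT", c3 = "AAAA"))
  expect_equal(homopolymer_length(ref, "c1", 4), 6L)
  expect_equal(homopolymer_length(ref, "c2", 2), 1L)
  expect_equal(homopolymer_length(ref, "c3", 1), 4L)
  expect_error(homopolymer_length(ref, "c2", 5), class = "nbsval_bounds")
})

test_that("reference sequences validate their alphabet and names", {
  expect_error(ref_seqs(c("ACGT")), class = "nbsval_bad_reference")
  expect_error(ref_seqs(c(c1 = "ACXT")), class = "nbsval_bad_reference")
  expect_equal(unclass(ref_seqs(c(c1 = "acgt")))[["c1"]], "ACGT")
})
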