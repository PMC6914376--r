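#' Confusion matrix against a truth set
#'
#' @param tp,fp,fn,tn non-negative counts. `tn` counts panel positions
#'   correctly reported as reference (base-level accounting), not alleles.
#' @return a `confusion` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(is_count(tp), is_count(fp), is_count(fn), is_count(tn),
            tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %s  FP %s  FN %s  TN %s\n",
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$fn, big.mark = ","), format(x$tn, big.mark = ",")))
  invisible(x)
}

#' Compare a query call set to a truth set over a panel
#'
#' Allele-level matching on the key (contig, pos, ref, alt) after
#' normalization; genotype is deliberately not part of the key (zygosity
#' mismatches are annotated separately, not double-counted as FP+FN).
#' True negatives are counted at base level: every panel position not
#' covered by the reference footprint of any TP/FP/FN event counts once
#' as a correctly-reported reference base, so that when every event
#' occupies a distinct single position, `tp + fp + fn + tn` equals the
#' panel size in bases.
#'
#' @param query,truth normalized, panel-restricted variant data.frames.
#' @param panel a [build_panel()] result.
#' @param genotype_aware also require genotype to match (default FALSE);
#'   with allele-level matching, zygosity mismatches are listed in the
#'   `zygosity_mismatches` attribute instead.
#' @return a `confusion` object with attributes `tp_keys`, `fp_calls`,
#'   `fn_calls`, `zygosity_mismatches`.
#' @export
compare_to_truth <- function(query, truth, panel, genotype_aware = FALSE) {
  assert_normalized_shape(query, "query calls")
  assert_normalized_shape(truth, "truth calls")
  qk <- variant_key(query)
  tk <- variant_key(truth)
  if (genotype_aware) {
    qk <- paste(qk, query$genotype, sep = ":")
    tk <- paste(tk, truth$genotype, sep = ":")
  }
  tp_idx <- qk %in% tk
  fp <- query[!tp_idx, , drop = FALSE]
  fn <- truth[!(tk %in% qk), , drop = FALSE]
  events <- rbind(variant_footprint(query[tp_idx, , drop = FALSE]),
                  variant_footprint(fp), variant_footprint(fn))
  consumed <- if (nrow(events)) {
    length(panel_positions_in(panel, events$contig, events$start, events$end))
  } else 0L
  cm <- confusion_matrix(tp = sum(tp_idx), fp = nrow(fp), fn = nrow(fn),
                         tn = panel_total_bases(panel) - consumed)
  zyg <- if (!genotype_aware && sum(tp_idx)) {
    m <- match(qk[tp_idx], tk)
    mism <- query[tp_idx, , drop = FALSE][
      query$genotype[tp_idx] != truth$genotype[m], , drop = FALSE]
    mism
  } else empty_variants()
  attr(cm, "tp_keys") <- unique(qk[tp_idx])
  attr(cm, "fp_calls") <- fp
  attr(cm, "fn_calls") <- fn
  attr(cm, "zygosity_mismatches") <- zyg
  cm
}

#' Analytical sensitivity, specificity and MCC
#'
#' `sensitivity` is `100 * tp / (tp + fn)` and `specificity` is
#' `100 * tn / (tn + fp)`, both in percent over the base-level confusion
#' counts. `mcc` is the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that a zero denominator factor yields 0.
#'
#' @param cm a [confusion_matrix()] object.
#' @return a single numeric value (percent for sensitivity/specificity).
#' @examples
#' cm <- confusion_matrix(tp = 130, fp = 10, fn = 0, tn = 49905)
#' sensitivity(cm)  # 100
#' mcc(cm)          # ~0.9635
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0) {
    stopf("nbsval_undefined", "sensitivity undefined: tp + fn = 0")
  }
  100 * cm$tp / (cm$tp + cm$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0) {
    stopf("nbsval_undefined", "specificity undefined: tn + fp = 0")
  }
  100 * cm$tn / (cm$tn + cm$fp)
}

#' @rdname sensitivity
#' @export
mcc <- function(cm) {
  fac <- c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)
  if (any(fac == 0)) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(prod(fac))
}

#' Pool per-sample confusion matrices
#'
#' Counts are summed across samples; the pooled unique-matching-variant
#' count is the number of distinct TP keys across all samples.
#'
#' @param cms list of `confusion` objects from [compare_to_truth()].
#' @return a pooled `confusion` object with attribute `unique_tp_keys`.
#' @export
pool_confusion <- function(cms) {
  stopifnot(length(cms) > 0)
  cm <- confusion_matrix(
    tp = sum(vapply(cms, function(x) x$tp, numeric(1))),
    fp = sum(vapply(cms, function(x) x$fp, numeric(1))),
    fn = sum(vapply(cms, function(x) x$fn, numeric(1))),
    tn = sum(vapply(cms, function(x) x$tn, numeric(1)))
  )
  attr(cm, "unique_tp_keys") <-
    unique(unlist(lapply(cms, attr, "tp_keys"), use.names = FALSE))
  cm
}

#' Annotate false-positive context
#'
#' Flags each false-positive call that falls inside a declared short
#' tandem repeat interval (`in_STR`) or inside a homopolymer run of at
#' least `min_homopolymer` bases (`in_homopolymer`). Repetitive tracts
#' are where alignment and flow-space artifacts concentrate, so these
#' flags mark exclusion-eligible calls in validation reports.
#'
#' @param fp_calls variant data.frame of false positives.
#' @param ref a [ref_seqs()] object.
#' @param str_regions intervals (0-based half-open) of declared STRs.
#' @param min_homopolymer minimum run length to flag (default 5).
#' @return `fp_calls` with logical columns `in_STR` and `in_homopolymer`.
#' @export
flag_context <- function(fp_calls, ref, str_regions, min_homopolymer = 5L) {
  n <- nrow(fp_calls)
  fp_calls$in_STR <- logical(n)
  fp_calls$in_homopolymer <- logical(n)
  if (n == 0) return(fp_calls)
  fpf <- variant_footprint(fp_calls)
  for (i in seq_len(n)) {
    pos0 <- seq.int(fpf$start[i], fpf$end[i] - 1L)
    if (nrow(str_regions)) {
      fp_calls$in_STR[i] <- any(panel_contains(
        sort_intervals(str_regions), fpf$contig[i], pos0))
    }
    fp_calls$in_homopolymer[i] <-
      homopolymer_length(ref, fp_calls$contig[i], fp_calls$pos[i]) >=
        min_homopolymer
  }
  fp_calls
}

#' Assemble a validation report
#'
#' @param comparisons named list of per-sample [compare_to_truth()] results.
#' @param ref a [ref_seqs()] object (for FP context flags).
#' @param str_regions declared STR intervals (may be empty).
#' @return a `validation_report` list: pooled confusion, sensitivity,
#'   specificity, mcc, unique matching variant count, per-sample counts
#'   and the annotated FP breakdown.
#' @export
validation_report <- function(comparisons, ref = NULL,
                              str_regions = genomic_intervals()) {
  pooled <- pool_confusion(comparisons)
  fp_all <- do.call(rbind, c(list(empty_variants()),
                             lapply(comparisons, attr, "fp_calls")))
  fp_flagged <- if (!is.null(ref)) {
    flag_context(fp_all, ref, str_regions)
  } else fp_all
  per_sample <- data.frame(
    sample = names(comparisons) %||% as.character(seq_along(comparisons)),
    tp = vapply(comparisons, function(x) x$tp, numeric(1)),
    fp = vapply(comparisons, function(x) x$fp, numeric(1)),
    fn = vapply(comparisons, function(x) x$fn, numeric(1)),
    tn = vapply(comparisons, function(x) x$tn, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    confusion = pooled,
    sensitivity = sensitivity(pooled),
    specificity = specificity(pooled),
    mcc = mcc(pooled),
    unique_matching_variants = length(attr(pooled, "unique_tp_keys")),
    per_sample = per_sample,
    fp_breakdown = fp_flagged
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation against truth set\n")
  print(x$confusion)
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  MCC %.3f\n",
              x$sensitivity, x$specificity, x$mcc))
  cat(sprintf("  %d unique matching variant(s); %d false positive(s)\n",
              x$unique_matching_variants, nrow(x$fp_breakdown)))
  invisible(x)
}
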