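#' Variant-caller filter thresholds
#'
#' The thresholds applied by the screening pipeline's variant caller,
#' reproduced here as a deterministic post-hoc filter. Defaults are the
#' sensitivity-maximising settings used for the assay: minimum variant
#' score 10, minimum allele fraction 0.1, minimum coverage 10, no
#' per-strand coverage requirement, strand-bias checks disabled (maximum
#' strand bias 1, p-value 0), and a homopolymer length cap of 9 bp.
#'
#' @param min_qual minimum variant score.
#' @param min_allele_fraction minimum allele fraction.
#' @param min_depth minimum read depth at the call position.
#' @param min_depth_each_strand minimum per-strand depth.
#' @param max_strand_bias maximum tolerated strand bias (1 disables).
#' @param strand_bias_pvalue carried for config fidelity; at the default 0,
#'   together with `max_strand_bias = 1`, strand-bias rejection is a no-op.
#' @param max_homopolymer_len maximum homopolymer run length at the call
#'   position.
#' @param homopolymer_applies which variant classes the homopolymer cap is
#'   applied to (`"both"`, `"SNV"` or `"indel"`).
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_qual = 10, min_allele_fraction = 0.1,
                              min_depth = 10L, min_depth_each_strand = 0L,
                              max_strand_bias = 1, strand_bias_pvalue = 0,
                              max_homopolymer_len = 9L,
                              homopolymer_applies = c("both", "SNV", "indel")) {
  homopolymer_applies <- match.arg(homopolymer_applies)
  t <- list(min_qual = min_qual,
            min_allele_fraction = min_allele_fraction,
            min_depth = as.integer(min_depth),
            min_depth_each_strand = as.integer(min_depth_each_strand),
            max_strand_bias = max_strand_bias,
            strand_bias_pvalue = strand_bias_pvalue,
            max_homopolymer_len = as.integer(max_homopolymer_len),
            homopolymer_applies = homopolymer_applies)
  if (t$min_qual < 0 || t$min_allele_fraction < 0 ||
      t$min_allele_fraction > 1 || t$min_depth < 0 ||
      t$min_depth_each_strand < 0 || t$max_strand_bias < 0 ||
      t$max_strand_bias > 1 || t$max_homopolymer_len < 0) {
    stopf("nbsval_bad_config", "filter thresholds out of range")
  }
  structure(t, class = "filter_thresholds")
}

#' Apply caller thresholds to candidate calls
#'
#' A call passes iff `qual >= min_qual`, `allele_fraction >=
#' min_allele_fraction`, `depth >= min_depth`, each strand depth `>=
#' min_depth_each_strand`, `strand_bias <= max_strand_bias`, and the
#' homopolymer run length at the first base of the reference footprint is
#' `<= max_homopolymer_len`. Rejections carry the first failing criterion
#' in the fixed evaluation order qual, allele_fraction, depth,
#' strand_depth, strand_bias, homopolymer. NA fields never cause
#' rejection (a missing annotation cannot fail a threshold).
#'
#' @param candidates normalized variant data.frame.
#' @param thresholds a [filter_thresholds()] object.
#' @param ref a [ref_seqs()] object (homopolymer context).
#' @return list with elements `passed` (variant data.frame) and
#'   `rejected` (variant data.frame with a `reason` column); together they
#'   partition `candidates`, order preserved within each.
#' @export
filter_calls <- function(candidates, thresholds = filter_thresholds(), ref) {
  t <- thresholds
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)
  fail <- function(cur, bad, code) ifelse(is.na(cur) & bad, code, cur)
  ge <- function(x, lim) !is.na(x) & x < lim   # TRUE when threshold failed
  reason <- fail(reason, ge(candidates$qual, t$min_qual), "qual")
  reason <- fail(reason, ge(candidates$allele_fraction, t$min_allele_fraction),
                 "allele_fraction")
  reason <- fail(reason, ge(candidates$depth, t$min_depth), "depth")
  reason <- fail(reason, ge(candidates$depth_fwd, t$min_depth_each_strand) |
                         ge(candidates$depth_rev, t$min_depth_each_strand),
                 "strand_depth")
  reason <- fail(reason, !is.na(candidates$strand_bias) &
                         candidates$strand_bias > t$max_strand_bias,
                 "strand_bias")
  if (n > 0) {
    cls <- variant_class(candidates)
    hp <- vapply(seq_len(n), function(i) {
      # for anchored indels the first alt-affected base sits after the
      # shared anchor base, hence pos + 1 (clamped to the contig end)
      p <- candidates$pos[i]
      if (cls[i] == "indel") {
        p <- min(p + 1L, nchar(contig_seq(ref, candidates$contig[i])))
      }
      homopolymer_length(ref, candidates$contig[i], p)
    }, integer(1))
    applies <- switch(t$homopolymer_applies,
                      both = rep(TRUE, n),
                      SNV = cls == "SNV",
                      indel = cls == "indel")
    reason <- fail(reason, applies & hp > t$max_homopolymer_len, "homopolymer")
  }
  rejected <- candidates[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  list(passed = candidates[is.na(reason), , drop = FALSE],
       rejected = rejected)
}
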