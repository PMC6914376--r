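#' Biallelic variant records
#'
#' Variant calls are held as plain data frames, one row per biallelic
#' allele call, with columns:
#' \describe{
#'   \item{contig}{contig name}
#'   \item{pos}{1-based position of the first reference base}
#'   \item{ref, alt}{non-empty nucleotide strings, `ref != alt`}
#'   \item{genotype}{one of `"het"`, `"hom"`, `"unknown"`}
#'   \item{qual}{variant score, >= 0}
#'   \item{allele_fraction}{in `[0, 1]`}
#'   \item{depth}{reads at `pos`, >= 0}
#'   \item{depth_fwd, depth_rev}{per-strand depths}
#'   \item{strand_bias}{in `[0, 1]`}
#' }
#'
#' @param contig,pos,ref,alt,genotype,qual,allele_fraction,depth,depth_fwd,depth_rev,strand_bias
#'   field vectors, recycled to a common length.
#' @return a validated variant data.frame.
#' @export
variant_records <- function(contig, pos, ref, alt, genotype = "unknown",
                            qual = 100, allele_fraction = 0.5, depth = 100L,
                            depth_fwd = NA_integer_, depth_rev = NA_integer_,
                            strand_bias = 0.5) {
  n <- max(length(contig), length(pos), length(ref), length(alt))
  v <- data.frame(
    contig = rep_len(as.character(contig), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    genotype = rep_len(as.character(genotype), n),
    qual = rep_len(as.numeric(qual), n),
    allele_fraction = rep_len(as.numeric(allele_fraction), n),
    depth = rep_len(as.integer(depth), n),
    depth_fwd = rep_len(as.integer(depth_fwd), n),
    depth_rev = rep_len(as.integer(depth_rev), n),
    strand_bias = rep_len(as.numeric(strand_bias), n),
    stringsAsFactors = FALSE
  )
  validate_variants(v)
  v
}

empty_variants <- function() {
  variant_records(character(), integer(), character(), character())
}

validate_variants <- function(v, ref = NULL) {
  if (nrow(v) == 0) return(invisible(v))
  if (any(!nzchar(v$ref)) || any(!nzchar(v$alt))) {
    stopf("nbsval_bad_variant", "ref and alt must be non-empty")
  }
  if (any(v$ref == v$alt)) {
    stopf("nbsval_bad_variant", "ref must differ from alt")
  }
  if (any(v$pos < 1L)) {
    stopf("nbsval_bad_variant", "pos must be >= 1")
  }
  if (any(!v$genotype %in% c("het", "hom", "unknown"))) {
    stopf("nbsval_bad_variant", "genotype must be het/hom/unknown")
  }
  if (any(v$qual < 0, na.rm = TRUE) ||
      any(v$allele_fraction < 0 | v$allele_fraction > 1, na.rm = TRUE) ||
      any(v$depth < 0, na.rm = TRUE) ||
      any(v$strand_bias < 0 | v$strand_bias > 1, na.rm = TRUE)) {
    stopf("nbsval_bad_variant", "numeric fields out of range")
  }
  if (!is.null(ref)) {
    for (i in seq_len(nrow(v))) {
      seen <- ref_base(ref, v$contig[i], v$pos[i], nchar(v$ref[i]))
      if (seen != v$ref[i]) {
        stopf("nbsval_ref_mismatch",
              "ref allele '%s' at %s:%d does not match reference '%s'",
              v$ref[i], v$contig[i], v$pos[i], seen)
      }
    }
  }
  invisible(v)
}

#' Variant class (SNV vs indel)
#'
#' A record is an SNV iff both alleles are single bases; everything else
#' (after decomposition has split multi-base substitutions into per-base
#' SNVs) is an indel.
#'
#' @param v variant data.frame.
#' @return character vector `"SNV"`/`"indel"`.
#' @export
variant_class <- function(v) {
  ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "SNV", "indel")
}

#' Decompose multi-allelic calls into biallelic records
#'
#' Takes raw calls whose `alt` field may hold several comma-separated
#' alternate alleles and a VCF-style genotype index string (e.g. `"1/2"`),
#' and emits one biallelic record per alternate allele, in alt order.
#' Genotype of each output reflects only its own allele: present on both
#' haplotypes = `hom`, on one = `het`, missing indices = `unknown`.
#' Per-allele comma-separated `allele_fraction` values are split
#' alongside the alleles.
#'
#' @param raw data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (comma-separated), `gt` (index string such as `"0/1"`), and
#'   optionally `qual`, `allele_fraction` (comma-separated), `depth`,
#'   `depth_fwd`, `depth_rev`, `strand_bias`.
#' @return a biallelic variant data.frame (see [variant_records()]).
#' @examples
#' raw <- data.frame(contig = "c", pos = 100, ref = "A", alt = "G,T", gt = "1/2")
#' decompose(raw)
#' @export
decompose <- function(raw) {
  rows <- lapply(seq_len(nrow(raw)), function(i) decompose_one(raw[i, ]))
  out <- do.call(rbind, c(list(empty_variants()), rows))
  rownames(out) <- NULL
  out
}

decompose_one <- function(r) {
  alts <- strsplit(r$alt, ",", fixed = TRUE)[[1]]
  if (length(alts) < 1L) {
    stopf("nbsval_malformed", "call at %s:%d has no alt allele", r$contig, r$pos)
  }
  gt_raw <- if (!is.null(r$gt)) r$gt else "./."
  idx <- strsplit(gt_raw, "[/|]")[[1]]
  known <- idx[idx != "."]
  if (length(known)) {
    ik <- suppressWarnings(as.integer(known))
    if (any(is.na(ik)) || any(ik < 0) || any(ik > length(alts))) {
      stopf("nbsval_malformed",
            "genotype '%s' indexes alleles outside REF + %d ALT(s)",
            gt_raw, length(alts))
    }
  }
  afs <- rep(NA_real_, length(alts))
  if (!is.null(r$allele_fraction) && !is.na(r$allele_fraction)) {
    af_parts <- suppressWarnings(
      as.numeric(strsplit(as.character(r$allele_fraction), ",")[[1]]))
    afs <- rep_len(af_parts, length(alts))
  }
  per_alt <- lapply(seq_along(alts), function(a) {
    n_copies <- if (any(idx == ".")) NA_integer_ else sum(idx == as.character(a))
    geno <- if (is.na(n_copies)) "unknown"
            else if (n_copies >= 2L) "hom"
            else if (n_copies == 1L) "het"
            else "unknown"
    variant_records(
      contig = r$contig, pos = r$pos, ref = r$ref, alt = alts[a],
      genotype = geno,
      qual = r$qual %||% 100,
      allele_fraction = if (is.na(afs[a])) 0.5 else afs[a],
      depth = r$depth %||% 100L,
      depth_fwd = r$depth_fwd %||% NA_integer_,
      depth_rev = r$depth_rev %||% NA_integer_,
      strand_bias = r$strand_bias %||% 0.5
    )
  })
  do.call(rbind, per_alt)
}

# is (ref, alt) in left-aligned parsimonious shape (reference-free check)?
is_normalized_shape <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  last_shared <- substr(ref, nr, nr) == substr(alt, na, na)
  first_shared <- nr >= 2L & na >= 2L &
    substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  mnp <- nr == na & nr > 1L
  !(last_shared | first_shared | mnp)
}

#' Left-align and trim a single biallelic variant
#'
#' Implements the classic left-align-and-trim normalization: repeatedly
#' drop a shared rightmost base of ref and alt (extending both one base
#' leftward from the reference whenever either allele would become
#' empty), then drop shared leftmost bases while both alleles have at
#' least two bases. The result is the unique leftmost parsimonious
#' representation of the edit; applying it to the reference gives the
#' same edited sequence as the input, and the operation is idempotent.
#'
#' @param contig,pos,ref_allele,alt_allele the variant to normalize.
#' @param ref a [ref_seqs()] object.
#' @return list with elements `pos`, `ref`, `alt`.
#' @examples
#' ref <- ref_seqs(c(c1 = "GGGCACACACT"))
#' normalize_variant("c1", 4, "CACA", "CA", ref)  # pos 3, GCA -> G
#' @export
normalize_variant <- function(contig, pos, ref_allele, alt_allele, ref) {
  s <- contig_seq(ref, contig)
  pos <- as.integer(pos)
  r <- toupper(ref_allele); a <- toupper(alt_allele)
  if (!nzchar(r) || !nzchar(a)) {
    stopf("nbsval_bad_variant", "ref and alt must be non-empty")
  }
  seen <- substr(s, pos, pos + nchar(r) - 1L)
  if (seen != r) {
    stopf("nbsval_ref_mismatch",
          "ref allele '%s' at %s:%d does not match reference '%s'",
          r, contig, pos, seen)
  }
  repeat {
    nr <- nchar(r); na <- nchar(a)
    if (substr(r, nr, nr) == substr(a, na, na)) {
      r <- substr(r, 1L, nr - 1L)
      a <- substr(a, 1L, na - 1L)
      if (!nzchar(r) || !nzchar(a)) {
        if (pos <= 1L) {
          stopf("nbsval_left_extend",
                "normalization of %s:%d %s>%s walked past contig start",
                contig, as.integer(pos), ref_allele, alt_allele)
        }
        pos <- pos - 1L
        b <- substr(s, pos, pos)
        r <- paste0(b, r)
        a <- paste0(b, a)
      }
    } else break
  }
  while (nchar(r) >= 2L && nchar(a) >= 2L &&
         substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    r <- substr(r, 2L, nchar(r))
    a <- substr(a, 2L, nchar(a))
    pos <- pos + 1L
  }
  if (r == a) {
    stopf("nbsval_bad_variant", "alleles are identical after trimming")
  }
  list(pos = pos, ref = r, alt = a)
}

#' Normalize a table of biallelic calls
#'
#' Left-aligns and trims every record with [normalize_variant()], then
#' decomposes any remaining equal-length multi-base substitution into its
#' per-base SNVs (bases equal between the two alleles are dropped), so
#' that truth matching is representation-independent. Exact duplicate
#' records arising from normalization are collapsed.
#'
#' @param calls biallelic variant data.frame.
#' @param ref a [ref_seqs()] object.
#' @return normalized variant data.frame, sorted by (contig, pos, ref, alt).
#' @export
normalize_calls <- function(calls, ref) {
  if (nrow(calls) == 0) return(calls)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, , drop = FALSE]
    nv <- normalize_variant(v$contig, v$pos, v$ref, v$alt, ref)
    v$pos <- nv$pos; v$ref <- nv$ref; v$alt <- nv$alt
    if (nchar(v$ref) == nchar(v$alt) && nchar(v$ref) > 1L) {
      split_mnp(v)
    } else v
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(variant_key(out)), , drop = FALSE]
  out <- out[order(out$contig, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# split an equal-length multi-base substitution into per-base SNVs
split_mnp <- function(v) {
  rb <- strsplit(v$ref, "", fixed = TRUE)[[1]]
  ab <- strsplit(v$alt, "", fixed = TRUE)[[1]]
  diffs <- which(rb != ab)
  rows <- lapply(diffs, function(k) {
    w <- v
    w$pos <- v$pos + k - 1L
    w$ref <- rb[k]
    w$alt <- ab[k]
    w
  })
  do.call(rbind, rows)
}

# 0-based half-open reference footprint of each call
variant_footprint <- function(v) {
  data.frame(contig = v$contig,
             start = v$pos - 1L,
             end = v$pos - 1L + nchar(v$ref),
             stringsAsFactors = FALSE)
}

assert_normalized_shape <- function(v, what = "calls") {
  if (nrow(v) == 0) return(invisible(v))
  ok <- is_normalized_shape(v$ref, v$alt)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stopf("nbsval_precondition",
          "%s contain unnormalized record %s:%d %s>%s; run normalize_calls() first",
          what, v$contig[i], v$pos[i], v$ref[i], v$alt[i])
  }
  invisible(v)
}
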