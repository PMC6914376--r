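#' Read a VCF into a raw call table
#'
#' Parses a VCF v4.2 file (via `vcfR`) into a plain data.frame of raw,
#' possibly multi-allelic calls ready for [decompose()]. Recognized
#' per-sample FORMAT fields: `GT`, `AF` (per-alt allele fraction), `DP`
#' (depth), `SAF`/`SAR` (per-strand depths), `SB` (strand bias). Missing
#' fields are returned as NA.
#'
#' @param path VCF path (plain or bgzip/gzip).
#' @param sample name of the sample column to read; defaults to the first.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (comma-separated), `gt`, `qual`, `allele_fraction`, `depth`,
#'   `depth_fwd`, `depth_rev`, `strand_bias`, `filter`.
#' @export
read_vcf <- function(path, sample = NULL) {
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gt = character(), qual = numeric(),
                      allele_fraction = character(), depth = integer(),
                      depth_fwd = integer(), depth_rev = integer(),
                      strand_bias = numeric(), filter = character(),
                      stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty)
  n <- nrow(fix)
  fmt_field <- function(field) {
    if (ncol(x@gt) < 2) return(rep(NA_character_, n))
    sample_col <- if (is.null(sample)) 2L else {
      m <- match(sample, colnames(x@gt))
      if (is.na(m)) stopf("nbsval_malformed", "sample '%s' not in VCF", sample)
      m
    }
    keys <- strsplit(x@gt[, 1L], ":", fixed = TRUE)
    vals <- strsplit(x@gt[, sample_col], ":", fixed = TRUE)
    vapply(seq_len(n), function(i) {
      j <- match(field, keys[[i]])
      if (is.na(j) || j > length(vals[[i]])) NA_character_ else vals[[i]][j]
    }, character(1))
  }
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  int <- function(v) suppressWarnings(as.integer(ifelse(v == ".", NA, v)))
  data.frame(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    gt = {g <- fmt_field("GT"); ifelse(is.na(g), "./.", g)},
    qual = num(fix$QUAL),
    allele_fraction = fmt_field("AF"),
    depth = int(fmt_field("DP")),
    depth_fwd = int(fmt_field("SAF")),
    depth_rev = int(fmt_field("SAR")),
    strand_bias = num(fmt_field("SB")),
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    stringsAsFactors = FALSE
  )
}

#' Read, decompose and normalize a VCF in one step
#'
#' @inheritParams read_vcf
#' @param ref a [ref_seqs()] object used for normalization.
#' @return normalized biallelic variant data.frame.
#' @export
read_calls <- function(path, ref, sample = NULL) {
  normalize_calls(decompose(read_vcf(path, sample = sample)), ref)
}

fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))
fmt_int <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))

#' Write biallelic variant records to a VCF v4.2 file
#'
#' Writes plain (uncompressed) VCF with one sample column carrying
#' `GT:AF:DP:SAF:SAR:SB`. Output is deterministic: no timestamps, fixed
#' number formatting, so identical record tables produce byte-identical
#' files. Fields the writer owns round-trip exactly through [read_vcf()]
#' + [decompose()] for values with short decimal representations.
#'
#' @param calls biallelic variant data.frame (see [variant_records()]).
#' @param path output path.
#' @param ref optional [ref_seqs()] used to emit `##contig` header lines.
#' @param sample_id sample column name.
#' @param filter per-record FILTER strings (default `"PASS"`), e.g. the
#'   rejection reason codes from [filter_calls()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, ref = NULL, sample_id = "SAMPLE",
                      filter = NULL) {
  filter <- filter %||% rep("PASS", nrow(calls))
  stopifnot(length(filter) == nrow(calls))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=nbsval",
    if (!is.null(ref)) {
      sprintf("##contig=<ID=%s,length=%d>", names(ref), nchar(unclass(ref)))
    },
    sprintf("##FILTER=<ID=%s,Description=\"%s\">",
            setdiff(unique(filter), "PASS"),
            "Rejected by threshold filter"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=SAF,Number=1,Type=Integer,Description=\"Forward strand depth\">",
    "##FORMAT=<ID=SAR,Number=1,Type=Integer,Description=\"Reverse strand depth\">",
    "##FORMAT=<ID=SB,Number=1,Type=Float,Description=\"Strand bias\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  gt_str <- c(het = "0/1", hom = "1/1", unknown = "./.")[calls$genotype]
  body <- if (nrow(calls) == 0) character(0) else paste(
    calls$contig, calls$pos, ".", calls$ref, calls$alt,
    fmt_num(calls$qual), filter, ".",
    "GT:AF:DP:SAF:SAR:SB",
    paste(gt_str, fmt_num(calls$allele_fraction), fmt_int(calls$depth),
          fmt_int(calls$depth_fwd), fmt_int(calls$depth_rev),
          fmt_num(calls$strand_bias), sep = ":"),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
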