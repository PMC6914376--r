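#' Reference sequences
#'
#' A reference sequence set is a named character vector of uppercase
#' nucleotide strings (alphabet `A/C/G/T/N`), one element per contig.
#' Variant positions are addressed 1-based inclusive against these strings.
#'
#' @param sequences named character vector of nucleotide strings.
#' @return an object of class `ref_seqs`.
#' @examples
#' ref <- ref_seqs(c(chr1 = "ACGTACGT"))
#' ref_base(ref, "chr1", 3)
#' @export
ref_seqs <- function(sequences) {
  if (length(sequences) == 0 || is.null(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stopf("nbsval_bad_reference", "reference needs at least one named contig")
  }
  nm <- names(sequences)
  sequences <- toupper(as.character(sequences))
  names(sequences) <- nm
  if (any(!nzchar(sequences))) {
    stopf("nbsval_bad_reference", "empty contig sequence")
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stopf("nbsval_bad_reference",
          "contig %s contains characters outside A/C/G/T/N",
          names(sequences)[bad][1])
  }
  structure(sequences, class = "ref_seqs")
}

#' @export
print.ref_seqs <- function(x, ...) {
  cat(sprintf("<ref_seqs> %d contig(s), %s bases total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

contig_seq <- function(ref, contig) {
  if (!contig %in% names(ref)) {
    stopf("nbsval_bounds", "contig '%s' not in reference", contig)
  }
  unclass(ref)[[contig]]
}

#' Fetch reference bases
#'
#' @param ref a [ref_seqs()] object.
#' @param contig contig name.
#' @param pos 1-based start position.
#' @param len number of bases (default 1).
#' @return character string of `len` bases.
#' @export
ref_base <- function(ref, contig, pos, len = 1L) {
  s <- contig_seq(ref, contig)
  if (pos < 1 || pos + len - 1 > nchar(s)) {
    stopf("nbsval_bounds", "position %d(+%d) outside contig %s (length %d)",
          pos, len - 1L, contig, nchar(s))
  }
  substr(s, pos, pos + len - 1L)
}

#' Length of the homopolymer run containing a position
#'
#' Returns the length of the maximal run of a single nucleotide that
#' contains the query position. Used both for the variant-caller
#' homopolymer-length filter (runs longer than the cap are a known error
#' mode of semiconductor sequencing) and for annotating false-positive
#' context.
#'
#' @inheritParams ref_base
#' @param pos 1-based position within the contig.
#' @return integer run length (>= 1).
#' @examples
#' ref <- ref_seqs(c(c1 = "GTTTTTTC"))
#' homopolymer_length(ref, "c1", 4)  # 6
#' @export
homopolymer_length <- function(ref, contig, pos) {
  s <- contig_seq(ref, contig)
  n <- nchar(s)
  if (pos < 1 || pos > n) {
    stopf("nbsval_bounds", "position %d outside contig %s (length %d)",
          pos, contig, n)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  b <- chars[pos]
  lo <- pos
  while (lo > 1L && chars[lo - 1L] == b) lo <- lo - 1L
  hi <- pos
  while (hi < n && chars[hi + 1L] == b) hi <- hi + 1L
  hi - lo + 1L
}

#' Locate all homopolymer runs of at least a given length
#'
#' @inheritParams ref_base
#' @param min_len minimum run length to report.
#' @return data.frame with columns `contig`, `start` (0-based), `end`
#'   (exclusive), `base`, `length`.
#' @export
homopolymer_runs <- function(ref, min_len = 5L) {
  out <- lapply(names(ref), function(ct) {
    s <- contig_seq(ref, ct)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$lengths >= min_len
    data.frame(
      contig = rep(ct, sum(keep)),
      start = starts[keep], end = ends[keep],
      base = r$values[keep], length = r$lengths[keep],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Read reference contigs from FASTA
#'
#' @param path path to a FASTA file.
#' @return a [ref_seqs()] object.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  # keep only the first word of the FASTA header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(x))
  ref_seqs(seqs)
}

#' Write reference contigs to FASTA
#'
#' @param ref a [ref_seqs()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
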