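#' Genomic intervals
#'
#' Intervals are plain data frames with columns `contig`, `start`, `end`,
#' using 0-based half-open coordinates throughout (the BED convention).
#' VCF positions are 1-based inclusive; conversion between the two happens
#' only at I/O and footprint boundaries, never in interval arithmetic.
#'
#' @param contig character vector of contig names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @return a data.frame of validated intervals.
#' @export
genomic_intervals <- function(contig = character(), start = integer(),
                              end = integer()) {
  iv <- data.frame(contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(all(c("contig", "start", "end") %in% names(iv)))
  if (any(is.na(iv$start)) || any(is.na(iv$end)) ||
      any(iv$start < 0) || any(iv$start >= iv$end)) {
    stopf("nbsval_bad_interval",
          "intervals must satisfy 0 <= start < end")
  }
  invisible(iv)
}

interval_lengths <- function(iv) iv$end - iv$start

sort_intervals <- function(iv) {
  iv[order(iv$contig, iv$start, iv$end), , drop = FALSE]
}

# merge overlapping or abutting intervals per contig (IRanges::reduce,
# with min.gapwidth = 1 so abutting intervals coalesce)
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  parts <- split(iv, iv$contig)
  merged <- lapply(names(parts), function(ct) {
    p <- parts[[ct]]
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    data.frame(contig = rep(ct, length(ir)),
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  sort_intervals(do.call(rbind, merged))
}

#' Build a padded, merged target panel
#'
#' Expands every exon by `padding_bp` on each side (clamped at position 0),
#' merges overlapping or abutting intervals per contig, and records the
#' total number of distinct targeted bases. This mirrors the design of
#' small screening panels targeting "exons plus a few flanking bases";
#' 3'UTR target regions are supplied simply as additional intervals.
#'
#' @param exons intervals as from [genomic_intervals()] (0-based half-open).
#' @param padding_bp non-negative integer padding added to both sides of
#'   each exon (default 5).
#' @param name panel name.
#' @return an object of class `panel`: merged sorted intervals plus
#'   attributes `name`, `padding_bp`, `total_bases`.
#' @examples
#' p <- build_panel(genomic_intervals("g1", c(10, 22), c(20, 30)), padding_bp = 5)
#' panel_total_bases(p)  # 30
#' @export
build_panel <- function(exons, padding_bp = 5L, name = "panel") {
  validate_intervals(exons)
  padding_bp <- as.integer(padding_bp)
  if (is.na(padding_bp) || padding_bp < 0) {
    stopf("nbsval_bad_interval", "padding_bp must be >= 0")
  }
  padded <- exons
  padded$start <- pmax(0L, padded$start - padding_bp)
  padded$end <- padded$end + padding_bp
  merged <- merge_intervals(padded)
  structure(merged,
            class = c("panel", "data.frame"),
            name = name, padding_bp = padding_bp,
            total_bases = sum(interval_lengths(merged)))
}

#' @rdname build_panel
#' @param panel a `panel` object.
#' @export
panel_total_bases <- function(panel) {
  attr(panel, "total_bases") %||% sum(interval_lengths(panel))
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel '%s'> %d interval(s), %s bases (padding %d bp)\n",
              attr(x, "name"), nrow(x),
              format(panel_total_bases(x), big.mark = ","),
              attr(x, "padding_bp") %||% NA_integer_))
  invisible(x)
}

#' Panel membership of single positions
#'
#' @param panel a [build_panel()] result (or plain merged intervals).
#' @param contig contig name(s).
#' @param pos_0based 0-based position(s).
#' @return logical vector: is each position inside the panel?
#' @export
panel_contains <- function(panel, contig, pos_0based) {
  n <- max(length(contig), length(pos_0based))
  contig <- rep_len(as.character(contig), n)
  pos_0based <- rep_len(as.integer(pos_0based), n)
  out <- logical(n)
  for (ct in unique(contig)) {
    p <- panel[panel$contig == ct, , drop = FALSE]
    sel <- contig == ct
    if (nrow(p) == 0) next
    # intervals are sorted and disjoint: binary search via findInterval
    idx <- findInterval(pos_0based[sel], p$start)
    hit <- idx >= 1L & pos_0based[sel] < p$end[pmax(idx, 1L)]
    out[sel] <- hit
  }
  out
}

# distinct panel positions overlapped by a 0-based half-open footprint;
# returns a character vector of "contig:pos0" keys
panel_positions_in <- function(panel, contig, start0, end0) {
  keys <- character(0)
  for (i in seq_along(contig)) {
    pos <- seq.int(start0[i], end0[i] - 1L)
    inside <- panel_contains(panel, contig[i], pos)
    if (any(inside)) {
      keys <- c(keys, paste(contig[i], pos[inside], sep = ":"))
    }
  }
  unique(keys)
}

#' Restrict variant calls to panel regions
#'
#' A call is retained when its reference footprint (`pos` to
#' `pos + nchar(ref) - 1`, 1-based) overlaps at least one panel base —
#' the same overlap semantics as a BED intersection of the call set with
#' the panel. Order of calls is preserved.
#'
#' @param calls a variant table (see [variant_records()]); calls should be
#'   normalized first so footprints are parsimonious.
#' @param panel a [build_panel()] result.
#' @return the retained subset of `calls`.
#' @export
restrict_calls <- function(calls, panel) {
  if (nrow(calls) == 0) return(calls)
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    start0 <- calls$pos[i] - 1L
    end0 <- start0 + nchar(calls$ref[i])
    any(panel_contains(panel, calls$contig[i], seq.int(start0, end0 - 1L)))
  }, logical(1))
  calls[keep, , drop = FALSE]
}

#' Read a BED file as panel intervals
#'
#' Track and browser lines are ignored; only the first three columns are
#' used. Coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @return intervals data.frame (0-based half-open), sorted.
#' @export
read_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  iv <- data.frame(contig = as.character(gr$seqnames),
                   start = as.integer(gr$start) - 1L,
                   end = as.integer(gr$end),
                   stringsAsFactors = FALSE)
  sort_intervals(validate_intervals(iv))
}

#' Write intervals to a 3-column BED file
#'
#' @param iv intervals (0-based half-open), e.g. a panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  df <- data.frame(iv$contig, iv$start, iv$end)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
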