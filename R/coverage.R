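#' Per-base coverage tracks
#'
#' A coverage track maps (contig, 0-based position) to read depth for one
#' sample, in the style of a per-base depth table produced by
#' `sambamba depth base`-like tools. Positions absent from the track are
#' treated as depth 0.
#'
#' @param contig,pos,depth vectors: contig, 0-based position, depth.
#' @param sample_id sample identifier.
#' @return a `coverage_track` data.frame with attribute `sample_id`.
#' @export
coverage_track <- function(contig, pos, depth, sample_id = "sample") {
  t <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                  depth = as.integer(depth), stringsAsFactors = FALSE)
  if (any(t$pos < 0) || any(t$depth < 0)) {
    stopf("nbsval_bad_config", "coverage positions and depths must be >= 0")
  }
  structure(t, class = c("coverage_track", "data.frame"),
            sample_id = sample_id)
}

#' Read per-base depth tables
#'
#' Accepts the long format `chrom  pos  depth  [sample_id]` (tab-separated,
#' 0-based positions, with or without a header line). When the file holds
#' several samples the result is a named list of tracks.
#'
#' @param path TSV path.
#' @return a single [coverage_track()] or a named list of them.
#' @export
read_depth_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom|contig", strsplit(first, "\t")[[1]][1],
                      ignore.case = TRUE)
  d <- read.table(path, sep = "\t", header = has_header,
                  stringsAsFactors = FALSE)
  if (!has_header) {
    names(d) <- c("chrom", "pos", "depth", "sample_id")[seq_len(ncol(d))]
  }
  if (ncol(d) < 3) {
    stopf("nbsval_malformed", "depth table needs >= 3 columns")
  }
  if (is.null(d$sample_id)) d$sample_id <- "sample"
  tracks <- lapply(split(d, d$sample_id), function(p) {
    coverage_track(p[[1]], p[[2]], p[[3]], sample_id = p$sample_id[1])
  })
  if (length(tracks) == 1L) tracks[[1]] else tracks
}

#' Write a per-base depth table
#'
#' @param track a [coverage_track()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  d <- data.frame(chrom = track$contig, pos = track$pos, depth = track$depth,
                  sample_id = attr(track, "sample_id") %||% "sample")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coverage QC policy
#'
#' Three-tier classification of samples by the percentage of panel bases
#' reaching a depth floor: below the first cutoff a sample has failed;
#' between the first and second it may have substantial gaps; between the
#' second and third, minor gaps; at or above the third, the sample is
#' unlikely to have substantial gaps. Boundary values belong to the
#' better tier.
#'
#' @param depth_threshold depth floor (default 50, i.e. "50x coverage",
#'   inclusive).
#' @param tier_cutoffs strictly increasing fractions in (0,1); defaults
#'   `c(0.90, 0.97, 0.995)`.
#' @return a `qc_policy` list.
#' @export
qc_policy <- function(depth_threshold = 50L,
                      tier_cutoffs = c(0.90, 0.97, 0.995)) {
  stopifnot(length(tier_cutoffs) == 3, all(diff(tier_cutoffs) > 0),
            all(tier_cutoffs > 0), all(tier_cutoffs < 1),
            depth_threshold > 0)
  structure(list(depth_threshold = as.integer(depth_threshold),
                 tier_cutoffs = as.numeric(tier_cutoffs)),
            class = "qc_policy")
}

qc_tiers <- c("fail", "may_have_gaps", "minor_gaps", "pass_clean")

panel_depths <- function(track, panel) {
  # depth at every panel position, absent positions = 0
  out <- integer(0)
  for (i in seq_len(nrow(panel))) {
    pos <- seq.int(panel$start[i], panel$end[i] - 1L)
    sub <- track[track$contig == panel$contig[i], , drop = FALSE]
    d <- sub$depth[match(pos, sub$pos)]
    d[is.na(d)] <- 0L
    out <- c(out, d)
  }
  out
}

#' Per-sample coverage QC
#'
#' Computes the percentage of panel bases with depth at or above the
#' policy's floor and assigns the QC tier.
#'
#' @param track a [coverage_track()].
#' @param panel a [build_panel()] result (nonempty).
#' @param policy a [qc_policy()].
#' @return a `sample_qc` list: `sample_id`, `pct_bases_at_depth`, `tier`.
#' @export
sample_qc <- function(track, panel, policy = qc_policy()) {
  total <- panel_total_bases(panel)
  if (is.null(total) || total == 0 || nrow(panel) == 0) {
    stopf("nbsval_bad_config", "panel is empty")
  }
  d <- panel_depths(track, panel)
  pct <- 100 * sum(d >= policy$depth_threshold) / total
  # tiny tolerance so boundary fractions are not pushed down a tier by
  # floating-point rounding of count ratios
  tier <- qc_tiers[1L + findInterval(pct / 100 + 1e-9, policy$tier_cutoffs)]
  structure(list(sample_id = attr(track, "sample_id") %||% "sample",
                 pct_bases_at_depth = pct, tier = tier,
                 policy = policy),
            class = "sample_qc")
}

#' Mean depth over a region
#'
#' @param track a [coverage_track()].
#' @param region one-row intervals data.frame (0-based half-open).
#' @return arithmetic mean depth over the region's positions.
#' @export
region_mean_coverage <- function(track, region) {
  validate_intervals(region)
  stopifnot(nrow(region) == 1)
  if (region$end - region$start < 1) {
    stopf("nbsval_bad_interval", "empty region")
  }
  d <- panel_depths(track, region)
  mean(d)
}

#' Run-level QC summary
#'
#' For each tier cutoff, reports the cumulative proportion of samples
#' whose percent-bases-at-depth is at or above it, together with
#' exclusive per-tier counts.
#'
#' @param samples list of [sample_qc()] results (nonempty).
#' @param policy a [qc_policy()] (defaults to the first sample's).
#' @return a `run_qc_summary` list: `n_samples`, `cumulative` (data.frame
#'   cutoff_pct / n_at_or_above / proportion_pct) and `tier_counts`.
#' @export
run_summary <- function(samples, policy = NULL) {
  if (length(samples) == 0) {
    stopf("nbsval_bad_config", "no samples to summarise")
  }
  policy <- policy %||% samples[[1]]$policy
  pct <- vapply(samples, function(s) s$pct_bases_at_depth, numeric(1))
  cuts <- 100 * policy$tier_cutoffs
  cum <- data.frame(
    cutoff_pct = cuts,
    n_at_or_above = vapply(cuts, function(cc) sum(pct >= cc - 1e-9), numeric(1))
  )
  cum$proportion_pct <- 100 * cum$n_at_or_above / length(pct)
  tiers <- factor(vapply(samples, function(s) s$tier, character(1)),
                  levels = qc_tiers)
  structure(list(n_samples = length(samples),
                 cumulative = cum,
                 tier_counts = table(tiers)),
            class = "run_qc_summary")
}

#' @export
print.run_qc_summary <- function(x, ...) {
  cat(sprintf("<run_qc_summary> %d samples\n", x$n_samples))
  for (i in seq_len(nrow(x$cumulative))) {
    cat(sprintf("  >= %.1f%% bases at depth: %d (%.1f%%)\n",
                x$cumulative$cutoff_pct[i], x$cumulative$n_at_or_above[i],
                x$cumulative$proportion_pct[i]))
  }
  invisible(x)
}
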