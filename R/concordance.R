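#' Concordance policy
#'
#' @param coverage_threshold depth at or below which a variant position is
#'   in the low stratum (default 30: strata are `<=30x` vs `>30x`).
#' @param high_coverage_threshold depth used for the stricter
#'   "high coverage" summary column (default 50).
#' @param denominator `"union"` scores concordance as the matching
#'   fraction of all distinct variants seen in either member,
#'   `|A∩B| / |A∪B|`; `"mean_size"` uses `2|A∩B| / (|A|+|B|)` for
#'   sensitivity analysis.
#' @return a `concordance_policy` list.
#' @export
concordance_policy <- function(coverage_threshold = 30L,
                               high_coverage_threshold = 50L,
                               denominator = c("union", "mean_size")) {
  denominator <- match.arg(denominator)
  stopifnot(coverage_threshold > 0, high_coverage_threshold > 0)
  structure(list(coverage_threshold = as.integer(coverage_threshold),
                 high_coverage_threshold = as.integer(high_coverage_threshold),
                 denominator = denominator),
            class = "concordance_policy")
}

depth_at <- function(track, contig, pos_0based) {
  key <- paste(contig, pos_0based, sep = ":")
  d <- track$depth[match(key, paste(track$contig, track$pos, sep = ":"))]
  d
}

#' Compare paired call sets from two specimen types
#'
#' Matches variants between the two members of a pair (e.g. dried blood
#' spot vs venous blood from the same individual) on the normalized key
#' (contig, pos, ref, alt). Concordance is the fraction of matching
#' variants; each union-minus-intersection variant becomes one
#' discordance event classified by direction (`only_in_A`/`only_in_B`),
#' variant class, and coverage stratum. The stratum is derived from the
#' *minimum* of the two samples' depths at the variant position — a
#' variant is only reliably assessable when both members clear the depth
#' floor.
#'
#' @param calls_A,calls_B normalized, panel-restricted variant data.frames.
#' @param depth_A,depth_B coverage tracks (see [coverage_track()])
#'   covering every call position.
#' @param policy a [concordance_policy()].
#' @param name_A,name_B labels for the two members (for reports).
#' @return a `paired_comparison` list: `variants` (union table with
#'   membership, depths, class, stratum), `events` (discordance events),
#'   `n_calls_total`, `n_concordant_unique`, `concordance_all_pct`,
#'   `concordance_high_cov_pct`, `per_category_counts`.
#' @export
compare_pair <- function(calls_A, calls_B, depth_A, depth_B,
                         policy = concordance_policy(),
                         name_A = "A", name_B = "B") {
  assert_normalized_shape(calls_A, "calls_A")
  assert_normalized_shape(calls_B, "calls_B")
  ka <- variant_key(calls_A); kb <- variant_key(calls_B)
  all_k <- unique(c(ka, kb))
  src <- rbind(calls_A, calls_B)
  u <- src[match(all_k, variant_key(src)), , drop = FALSE]
  rownames(u) <- NULL
  in_A <- all_k %in% ka
  in_B <- all_k %in% kb
  cov_A <- depth_at(depth_A, u$contig, u$pos - 1L)
  cov_B <- depth_at(depth_B, u$contig, u$pos - 1L)
  if (nrow(u) && (any(is.na(cov_A)) || any(is.na(cov_B)))) {
    i <- which(is.na(cov_A) | is.na(cov_B))[1]
    stopf("nbsval_data_integrity",
          "no depth recorded at call position %s:%d", u$contig[i], u$pos[i])
  }
  min_cov <- pmin(cov_A, cov_B)
  variants <- data.frame(
    key = all_k, contig = u$contig, pos = u$pos, ref = u$ref, alt = u$alt,
    class = if (nrow(u)) variant_class(u) else character(0),
    in_A = in_A, in_B = in_B, concordant = in_A & in_B,
    coverage_A = cov_A, coverage_B = cov_B, min_coverage = min_cov,
    stratum = as.character(ifelse(min_cov > policy$coverage_threshold,
                                  "high", "low")),
    stringsAsFactors = FALSE
  )
  conc_pct <- function(sub) {
    n_union <- nrow(sub)
    n_int <- sum(sub$concordant)
    denom <- switch(policy$denominator,
                    union = n_union,
                    mean_size = (sum(sub$in_A) + sum(sub$in_B)) / 2)
    if (denom == 0) NA_real_ else 100 * n_int / denom
  }
  ev <- variants[!variants$concordant, , drop = FALSE]
  events <- data.frame(
    key = ev$key, contig = ev$contig, pos = ev$pos, ref = ev$ref,
    alt = ev$alt,
    direction = as.character(ifelse(ev$in_A, "only_in_A", "only_in_B")),
    class = ev$class, stratum = ev$stratum,
    coverage_A = ev$coverage_A, coverage_B = ev$coverage_B,
    stringsAsFactors = FALSE
  )
  per_cat <- if (nrow(events)) {
    as.data.frame(table(direction = events$direction, class = events$class,
                        stratum = events$stratum),
                  responseName = "n", stringsAsFactors = FALSE)
  } else {
    data.frame(direction = character(), class = character(),
               stratum = character(), n = integer(), stringsAsFactors = FALSE)
  }
  structure(list(
    name_A = name_A, name_B = name_B,
    variants = variants, events = events,
    n_calls_total = length(ka) + length(kb),
    n_concordant_unique = sum(variants$concordant),
    concordance_all_pct = conc_pct(variants),
    concordance_high_cov_pct =
      conc_pct(variants[variants$stratum == "high", , drop = FALSE]),
    per_category_counts = per_cat[per_cat$n > 0, , drop = FALSE],
    policy = policy
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison %s vs %s> %d calls, %d concordant unique\n",
              x$name_A, x$name_B, x$n_calls_total, x$n_concordant_unique))
  cat(sprintf("  concordance all %.1f%%, high-coverage %.1f%%; %d event(s)\n",
              x$concordance_all_pct, x$concordance_high_cov_pct,
              nrow(x$events)))
  invisible(x)
}

#' Summarise concordance across a cohort of pairs
#'
#' @param pairs list of [compare_pair()] results.
#' @return a `cohort_concordance` list with the mean per-pair concordance
#'   (all regions and high-coverage stratum), total call counts (summed,
#'   union and concordant-unique), and pooled per-category discordance
#'   counts.
#' @export
cohort_concordance <- function(pairs) {
  stopifnot(length(pairs) > 0)
  all_pct <- vapply(pairs, function(p) p$concordance_all_pct, numeric(1))
  high_pct <- vapply(pairs, function(p) p$concordance_high_cov_pct, numeric(1))
  events <- do.call(rbind, lapply(pairs, function(p) p$events))
  per_cat <- if (!is.null(events) && nrow(events)) {
    as.data.frame(table(direction = events$direction, class = events$class,
                        stratum = events$stratum),
                  responseName = "n", stringsAsFactors = FALSE)
  } else {
    data.frame(direction = character(), class = character(),
               stratum = character(), n = integer(), stringsAsFactors = FALSE)
  }
  structure(list(
    n_pairs = length(pairs),
    mean_concordance_all_pct = mean(all_pct, na.rm = TRUE),
    mean_concordance_high_cov_pct = mean(high_pct, na.rm = TRUE),
    n_calls_total = sum(vapply(pairs, function(p) p$n_calls_total, numeric(1))),
    n_calls_union = sum(vapply(pairs, function(p) nrow(p$variants), numeric(1))),
    n_concordant_unique =
      sum(vapply(pairs, function(p) p$n_concordant_unique, numeric(1))),
    per_category_counts = per_cat[per_cat$n > 0, , drop = FALSE],
    per_pair = data.frame(pair = seq_along(pairs),
                          concordance_all_pct = all_pct,
                          concordance_high_cov_pct = high_pct)
  ), class = "cohort_concordance")
}

#' @export
print.cohort_concordance <- function(x, ...) {
  cat(sprintf("<cohort_concordance> %d pairs, %d calls\n",
              x$n_pairs, x$n_calls_total))
  cat(sprintf("  mean concordance: all regions %.1f%%, high coverage %.1f%%\n",
              x$mean_concordance_all_pct, x$mean_concordance_high_cov_pct))
  invisible(x)
}

#' All-regions vs high-coverage concordance summary table
#'
#' Recomputes per-pair concordance restricted to variants whose minimum
#' coverage across the pair exceeds `threshold` (default the policy's
#' `high_coverage_threshold`), alongside the all-regions figure — the
#' two-column summary used to display paired specimen-type agreement.
#'
#' @param pairs list of [compare_pair()] results.
#' @param threshold depth floor for the restricted column.
#' @return data.frame with one row per pair plus a `mean` row.
#' @export
concordance_summary_table <- function(pairs, threshold = NULL) {
  stopifnot(length(pairs) > 0)
  thr <- threshold %||% pairs[[1]]$policy$high_coverage_threshold
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    v <- p$variants
    hv <- v[v$min_coverage > thr, , drop = FALSE]
    data.frame(pair = i,
               all_regions_pct = p$concordance_all_pct,
               high_coverage_pct =
                 if (nrow(hv)) 100 * sum(hv$concordant) / nrow(hv) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(pair = NA,
                        all_regions_pct = mean(tab$all_regions_pct, na.rm = TRUE),
                        high_coverage_pct = mean(tab$high_coverage_pct, na.rm = TRUE)))
}
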