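# Seeded synthetic-data generator: reference contigs with repeat tracts,
# padded exon panels, truth sets, paired error-injected call sets and
# per-base depth tracks, plus a ground-truth ledger that exactly
# describes everything emitted (the basis of the recovery tests).

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a five-gene newborn-screening
#' panel: ~50 kb of padded exonic target, truth sets dominated by SNVs
#' with a couple of indels, 33 paired dried-blood-spot (DBS) / venous
#' blood (VB) samples whose call sets carry coverage-dependent false
#' negatives, rare low-allele-fraction false-positive SNVs, and
#' false-positive indels confined to a poly-T tract. Depth is modelled
#' per amplicon-like window with negative-binomial dispersion; windows in
#' the low-coverage regime are clamped to 10-30x (so they sit in the
#' <=30x stratum yet still clear the caller's minimum-coverage filter)
#' and well-covered windows are floored at 35x, making stratum membership
#' deterministic by construction.
#'
#' @param seed integer seed fixing all randomness end-to-end.
#' @param n_genes number of gene contigs.
#' @param exons_per_gene exons per gene.
#' @param exon_len_mean,exon_len_sd,exon_len_min exon length distribution.
#' @param intron_len spacer between exons.
#' @param panel_padding bases added each side of each exon (default 5).
#' @param target_panel_bases intended panel size (scale contract: the
#'   generated panel lands within 5% of this).
#' @param n_truth_snvs,n_truth_indels truth-set composition.
#' @param truth_indel_del_len deletion length of truth indels.
#' @param fraction_low_coverage fraction of depth windows in the
#'   systematically-low regime.
#' @param window_bp amplicon-surrogate window width.
#' @param depth_mean_normal,depth_mean_low,depth_dispersion negative
#'   binomial depth model per window.
#' @param depth_floor_normal,depth_low_min,depth_low_max regime clamps.
#' @param p_fn_low,p_fn_high per-variant false-negative probability in
#'   low/high coverage windows.
#' @param fp_snv_rate expected false-positive SNVs per sample (Poisson).
#' @param fp_indel_polyt_rate expected false-positive indels per DBS
#'   sample, placed in the panel's poly-T tract (Poisson).
#' @param fp_indel_polyt_rate_vb same for VB samples (default 0; this
#'   artifact class is characteristic of the DBS libraries).
#' @param fp_low_bias probability that a false-positive SNV is placed in
#'   a low-coverage window.
#' @param n_pairs number of DBS/VB sample pairs.
#' @param polyt_lengths lengths of embedded poly-T tracts (first is the
#'   in-panel indel-artifact site and must be <= 9; one >= 10 exercises
#'   the caller's homopolymer cap).
#' @param str_unit,str_reps embedded short-tandem-repeat tract.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 5L, exons_per_gene = 12L,
                       exon_len_mean = 820, exon_len_sd = 150,
                       exon_len_min = 50L, intron_len = 300L,
                       panel_padding = 5L, target_panel_bases = 50000L,
                       n_truth_snvs = 46L, n_truth_indels = 2L,
                       truth_indel_del_len = 3L,
                       fraction_low_coverage = 0.04, window_bp = 150L,
                       depth_mean_normal = 200, depth_mean_low = 20,
                       depth_dispersion = 8, depth_floor_normal = 35L,
                       depth_low_min = 10L, depth_low_max = 30L,
                       p_fn_low = 0.4, p_fn_high = 0.005,
                       fp_snv_rate = 0.12, fp_indel_polyt_rate = 0.15,
                       fp_indel_polyt_rate_vb = 0,
                       fp_low_bias = 0.75, n_pairs = 33L,
                       polyt_lengths = c(8L, 10L),
                       str_unit = "CA", str_reps = 12L) {
  cfg <- as.list(environment())
  probs <- c(cfg$fraction_low_coverage, cfg$p_fn_low, cfg$p_fn_high,
             cfg$fp_low_bias)
  if (any(probs < 0 | probs > 1)) {
    stopf("nbsval_bad_config", "probabilities must lie in [0,1]")
  }
  if (cfg$polyt_lengths[1] > 9L) {
    stopf("nbsval_bad_config",
          "first poly-T tract is the indel-artifact site and must be <= 9 bp")
  }
  cfg$seed <- as.integer(seed) %% 2147483647L
  structure(cfg, class = "sim_config")
}

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# per-position homopolymer run length for one contig string
hp_length_vector <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  rep.int(r$lengths, r$lengths)
}

#' Generate reference contigs, exons and repeat tracts
#'
#' One contig per gene, uniform base composition, with exon coordinates
#' laid out along each contig. A short-tandem-repeat tract and the
#' configured poly-T tracts are embedded inside exons (so that calls in
#' them fall within the panel), and their coordinates are returned for
#' context annotation. Fully deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `ref` ([ref_seqs()]), `exons` (0-based intervals),
#'   `str_regions`, `polyt_regions`, and `hp_vectors` (per-contig
#'   homopolymer run length lookups).
#' @export
make_reference <- function(cfg = sim_config()) {
  local_seed(cfg$seed, {
    bases <- c("A", "C", "G", "T")
    contigs <- character(0)
    exon_rows <- list()
    for (g in seq_len(cfg$n_genes)) {
      name <- sprintf("gene%02d", g)
      lens <- pmax(cfg$exon_len_min,
                   round(rnorm(cfg$exons_per_gene, cfg$exon_len_mean,
                               cfg$exon_len_sd)))
      seq_parts <- character(0)
      cursor <- 0L
      for (e in seq_along(lens)) {
        intron <- paste(sample(bases, cfg$intron_len, replace = TRUE),
                        collapse = "")
        exon <- paste(sample(bases, lens[e], replace = TRUE), collapse = "")
        seq_parts <- c(seq_parts, intron, exon)
        start0 <- cursor + cfg$intron_len
        exon_rows[[length(exon_rows) + 1L]] <-
          data.frame(contig = name, start = start0, end = start0 + lens[e],
                     stringsAsFactors = FALSE)
        cursor <- start0 + lens[e]
      }
      tail_sp <- paste(sample(bases, cfg$intron_len, replace = TRUE),
                       collapse = "")
      contigs[name] <- paste0(paste(seq_parts, collapse = ""), tail_sp)
    }
    exons <- do.call(rbind, exon_rows)

    embed <- function(contig, tract) {
      # place the tract mid-exon on the given contig; returns 0-based iv
      ex <- exons[exons$contig == contig, , drop = FALSE]
      ex <- ex[(ex$end - ex$start) > nchar(tract) + 20L, , drop = FALSE]
      row <- ex[sample(nrow(ex), 1L), ]
      at0 <- row$start + 10L +
        sample(row$end - row$start - nchar(tract) - 20L, 1L)
      s <- contigs[[contig]]
      substr(s, at0 + 1L, at0 + nchar(tract)) <- tract
      contigs[[contig]] <<- s
      data.frame(contig = contig, start = at0, end = at0 + nchar(tract),
                 stringsAsFactors = FALSE)
    }
    str_tract <- paste(rep(cfg$str_unit, cfg$str_reps), collapse = "")
    str_regions <- embed(names(contigs)[1], str_tract)
    polyt_regions <- do.call(rbind, lapply(seq_along(cfg$polyt_lengths),
      function(i) {
        ct <- names(contigs)[1L + (i %% cfg$n_genes)]
        iv <- embed(ct, paste(rep("T", cfg$polyt_lengths[i]), collapse = ""))
        # flank the tract with non-T bases so the run length is exact
        s <- contigs[[ct]]
        if (iv$start >= 1L && substr(s, iv$start, iv$start) == "T") {
          substr(s, iv$start, iv$start) <- "G"
        }
        if (iv$end < nchar(s) && substr(s, iv$end + 1L, iv$end + 1L) == "T") {
          substr(s, iv$end + 1L, iv$end + 1L) <- "C"
        }
        contigs[[ct]] <<- s
        iv$length <- cfg$polyt_lengths[i]
        iv
      }))
    ref <- ref_seqs(contigs)
    list(ref = ref, exons = exons, str_regions = str_regions,
         polyt_regions = polyt_regions,
         hp_vectors = lapply(unclass(ref), hp_length_vector))
  })
}

# windows over panel intervals with systematic coverage regimes
make_windows <- function(cfg, panel) {
  rows <- list()
  wid <- 0L
  for (i in seq_len(nrow(panel))) {
    starts <- seq.int(panel$start[i], panel$end[i] - 1L, by = cfg$window_bp)
    for (s in starts) {
      wid <- wid + 1L
      rows[[wid]] <- data.frame(
        contig = panel$contig[i], start = s,
        end = min(s + cfg$window_bp, panel$end[i]), window = wid,
        stringsAsFactors = FALSE)
    }
  }
  w <- do.call(rbind, rows)
  w$regime <- ifelse(runif(nrow(w)) < cfg$fraction_low_coverage,
                     "low", "normal")
  w
}

draw_depth_track <- function(cfg, windows, sample_id) {
  mu <- ifelse(windows$regime == "low", cfg$depth_mean_low,
               cfg$depth_mean_normal)
  d <- rnbinom(nrow(windows), size = cfg$depth_dispersion, mu = mu)
  d <- ifelse(windows$regime == "low",
              pmin(pmax(d, cfg$depth_low_min), cfg$depth_low_max),
              pmax(d, cfg$depth_floor_normal))
  lens <- windows$end - windows$start
  coverage_track(
    contig = rep(windows$contig, lens),
    pos = unlist(lapply(seq_len(nrow(windows)),
                        function(i) seq.int(windows$start[i],
                                            windows$end[i] - 1L))),
    depth = rep(d, lens),
    sample_id = sample_id
  )
}

#' Generate truth set, paired call sets and depth tracks
#'
#' Builds one shared truth set over the panel (the replicate design of a
#' validation cohort), then for each of `n_pairs` individuals emits a DBS
#' and a VB call set derived from the truth by dropping false negatives
#' (probability depending on the coverage regime at the variant) and
#' adding false positives (SNVs anywhere, biased to low-coverage windows;
#' indels only in the in-panel poly-T tract), together with per-base
#' depth tracks. The returned ledger exactly describes the injected
#' errors and their coverage strata as measurable from the emitted
#' tracks.
#'
#' @param cfg a [sim_config()].
#' @param refinfo a [make_reference()] result.
#' @param panel a [build_panel()] result built from `refinfo$exons`.
#' @return list with `truth` (normalized variant data.frame), `samples`
#'   (named list of normalized call data.frames), `depths` (named list of
#'   [coverage_track()]s), `pairs` (data.frame pair / sample ids),
#'   `windows`, and `ledger`.
#' @export
make_truth_and_calls <- function(cfg, refinfo, panel) {
  local_seed(cfg$seed + 1L, {
    ref <- refinfo$ref
    # eligible single positions: in panel, homopolymer run <= 5, outside
    # the declared STR / poly-T tracts
    pos_tab <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      data.frame(contig = panel$contig[i],
                 pos0 = seq.int(panel$start[i], panel$end[i] - 1L),
                 stringsAsFactors = FALSE)
    }))
    hp_at <- function(contig, pos0) {
      mapply(function(ct, p) refinfo$hp_vectors[[ct]][p + 1L], contig, pos0,
             USE.NAMES = FALSE)
    }
    special <- rbind(refinfo$str_regions[, c("contig", "start", "end")],
                     refinfo$polyt_regions[, c("contig", "start", "end")])
    in_special <- panel_contains(sort_intervals(special),
                                 pos_tab$contig, pos_tab$pos0)
    eligible <- pos_tab[!in_special & hp_at(pos_tab$contig, pos_tab$pos0) <= 5L,
                        , drop = FALSE]
    n_needed <- cfg$n_truth_snvs + cfg$n_truth_indels
    if (n_needed > nrow(eligible)) {
      stopf("nbsval_capacity",
            "config requests %d truth variants but only %d eligible panel positions",
            n_needed, nrow(eligible))
    }
    picks <- eligible[sample(nrow(eligible), n_needed), , drop = FALSE]

    other_base <- function(b) {
      vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
             character(1), USE.NAMES = FALSE)
    }
    snv_picks <- picks[seq_len(cfg$n_truth_snvs), , drop = FALSE]
    snv_ref <- mapply(function(ct, p) ref_base(ref, ct, p + 1L),
                      snv_picks$contig, snv_picks$pos0, USE.NAMES = FALSE)
    geno <- sample(c("het", "hom"), cfg$n_truth_snvs, replace = TRUE,
                   prob = c(0.6, 0.4))
    truth <- variant_records(
      contig = snv_picks$contig, pos = snv_picks$pos0 + 1L,
      ref = snv_ref, alt = other_base(snv_ref),
      genotype = geno, qual = 100,
      allele_fraction = ifelse(geno == "hom", 1, 0.5)
    )
    if (cfg$n_truth_indels > 0) {
      idel <- picks[cfg$n_truth_snvs + seq_len(cfg$n_truth_indels), ,
                    drop = FALSE]
      for (k in seq_len(nrow(idel))) {
        p1 <- idel$pos0[k] + 1L
        dlen <- cfg$truth_indel_del_len
        raw_ref <- ref_base(ref, idel$contig[k], p1, dlen + 1L)
        nv <- normalize_variant(idel$contig[k], p1, raw_ref,
                                substr(raw_ref, 1L, 1L), ref)
        # keep the anchor inside the panel so depth/regime lookups at the
        # call position are always defined
        if (!panel_contains(panel, idel$contig[k], nv$pos - 1L)) next
        truth <- rbind(truth, variant_records(
          contig = idel$contig[k], pos = nv$pos, ref = nv$ref, alt = nv$alt,
          genotype = "het", qual = 100, allele_fraction = 0.5))
      }
    }
    truth <- truth[!duplicated(variant_key(truth)), , drop = FALSE]
    truth <- truth[order(truth$contig, truth$pos, truth$ref, truth$alt), ,
                   drop = FALSE]
    rownames(truth) <- NULL

    windows <- make_windows(cfg, panel)
    regime_by_pos <- setNames(
      rep(windows$regime, windows$end - windows$start),
      paste(rep(windows$contig, windows$end - windows$start),
            unlist(lapply(seq_len(nrow(windows)),
                          function(i) seq.int(windows$start[i],
                                              windows$end[i] - 1L))),
            sep = ":"))
    truth_regime <- unname(regime_by_pos[paste(truth$contig, truth$pos - 1L,
                                               sep = ":")])
    truth_regime[is.na(truth_regime)] <- "normal"

    polyt <- refinfo$polyt_regions[1, ]
    polyt_anchor1 <- polyt$start  # 1-based position of base before the run
    fp_site_pool <- eligible[!paste(eligible$contig, eligible$pos0) %in%
                               paste(truth$contig, truth$pos - 1L), ,
                             drop = FALSE]
    fp_pool_regime <- regime_by_pos[paste(fp_site_pool$contig,
                                          fp_site_pool$pos0, sep = ":")]

    samples <- list()
    depths <- list()
    ledger_samples <- list()
    pair_rows <- list()
    ledger_pairs <- list()

    for (i in seq_len(cfg$n_pairs)) {
      ids <- sprintf("P%02d_%s", i, c("DBS", "VB"))
      used_fp_pos <- character(0)
      pair_calls <- list()
      pair_ledger <- list()
      for (j in 1:2) {
        sid <- ids[j]
        track <- draw_depth_track(cfg, windows, sid)
        depth_by_pos <- setNames(track$depth,
                                 paste(track$contig, track$pos, sep = ":"))
        p_fn <- ifelse(truth_regime == "low", cfg$p_fn_low, cfg$p_fn_high)
        dropped <- runif(nrow(truth)) < p_fn
        calls <- truth[!dropped, , drop = FALSE]

        fp_rate <- cfg$fp_snv_rate
        n_fp_snv <- stats::rpois(1L, fp_rate)
        fp_rows <- empty_variants()
        if (n_fp_snv > 0) {
          for (k in seq_len(n_fp_snv)) {
            want_low <- runif(1) < cfg$fp_low_bias
            cand <- fp_site_pool[
              (if (want_low) fp_pool_regime == "low"
               else fp_pool_regime == "normal") &
              !paste(fp_site_pool$contig, fp_site_pool$pos0) %in% used_fp_pos,
              , drop = FALSE]
            if (nrow(cand) == 0) next
            site <- cand[sample(nrow(cand), 1L), ]
            used_fp_pos <- c(used_fp_pos, paste(site$contig, site$pos0))
            rb <- ref_base(ref, site$contig, site$pos0 + 1L)
            fp_rows <- rbind(fp_rows, variant_records(
              contig = site$contig, pos = site$pos0 + 1L,
              ref = rb, alt = other_base(rb),
              genotype = "het", qual = round(runif(1, 15, 60), 1),
              allele_fraction = 0.15))
          }
        }
        indel_rate <- if (j == 1) cfg$fp_indel_polyt_rate
                      else cfg$fp_indel_polyt_rate_vb
        n_fp_indel <- stats::rpois(1L, indel_rate)
        if (n_fp_indel > 0 &&
            !paste(polyt$contig, polyt_anchor1 - 1L) %in% used_fp_pos) {
          b <- ref_base(ref, polyt$contig, polyt_anchor1)
          fp_rows <- rbind(fp_rows, variant_records(
            contig = polyt$contig, pos = polyt_anchor1,
            ref = b, alt = paste0(b, "T"),
            genotype = "het", qual = round(runif(1, 15, 40), 1),
            allele_fraction = 0.2))
          used_fp_pos <- c(used_fp_pos, paste(polyt$contig, polyt_anchor1 - 1L))
        }
        calls <- rbind(calls, fp_rows)
        calls$depth <- unname(depth_by_pos[paste(calls$contig, calls$pos - 1L,
                                                 sep = ":")])
        calls$depth_fwd <- calls$depth %/% 2L
        calls$depth_rev <- calls$depth - calls$depth_fwd
        calls$strand_bias <- 0.5
        calls <- calls[order(calls$contig, calls$pos, calls$ref, calls$alt), ,
                       drop = FALSE]
        rownames(calls) <- NULL
        samples[[sid]] <- calls
        depths[[sid]] <- track
        ledger_samples[[sid]] <- list(
          fn = variant_key(truth[dropped, , drop = FALSE]),
          fp = variant_key(fp_rows),
          fp_class = if (nrow(fp_rows)) variant_class(fp_rows) else character(0)
        )
        pair_calls[[j]] <- calls
        pair_ledger[[j]] <- ledger_samples[[sid]]
      }
      # expected pairwise discordance from the injected sets (set algebra)
      ka <- variant_key(pair_calls[[1]]); kb <- variant_key(pair_calls[[2]])
      disc <- c(setdiff(ka, kb), setdiff(kb, ka))
      da <- setNames(depths[[ids[1]]]$depth,
                     paste(depths[[ids[1]]]$contig, depths[[ids[1]]]$pos,
                           sep = ":"))
      db <- setNames(depths[[ids[2]]]$depth,
                     paste(depths[[ids[2]]]$contig, depths[[ids[2]]]$pos,
                           sep = ":"))
      disc_tab <- if (length(disc)) {
        parts <- strsplit(disc, ":", fixed = TRUE)
        poskey <- vapply(parts, function(x) paste(x[1], as.integer(x[2]) - 1L,
                                                  sep = ":"), character(1))
        mincov <- pmin(unname(da[poskey]), unname(db[poskey]))
        data.frame(key = disc,
                   direction = ifelse(disc %in% ka, "only_in_A", "only_in_B"),
                   stratum = ifelse(mincov > 30L, "high", "low"),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(key = character(), direction = character(),
                   stratum = character(), stringsAsFactors = FALSE)
      }
      pair_rows[[i]] <- data.frame(pair = i, sample_A = ids[1],
                                   sample_B = ids[2],
                                   stringsAsFactors = FALSE)
      ledger_pairs[[i]] <- list(sample_A = ids[1], sample_B = ids[2],
                                discordant = disc_tab)
    }

    list(truth = truth, samples = samples, depths = depths,
         pairs = do.call(rbind, pair_rows), windows = windows,
         ledger = list(truth_keys = variant_key(truth),
                       samples = ledger_samples, pairs = ledger_pairs))
  })
}

#' Generate a coverage-QC cohort with prescribed tier membership
#'
#' Constructs depth tracks over a small dedicated panel such that exactly
#' the requested cumulative numbers of samples reach each tier cutoff.
#' `cumulative_counts` gives, for the cutoffs in ascending order, how
#' many samples are at or above each (so the counts are non-increasing
#' from the lowest cutoff to the highest when read that way; supply them
#' as `c(n_at_top_cutoff, n_at_mid, n_at_low)` nested upward, e.g.
#' `c(225, 264, 281)` of 288).
#'
#' @param n_samples cohort size (> 0).
#' @param cumulative_counts samples at or above the highest, middle and
#'   lowest cutoff respectively; must be non-decreasing and `<= n_samples`.
#' @param policy a [qc_policy()].
#' @param panel_bases size of the QC panel used for the construction.
#' @param seed RNG seed.
#' @return list with `panel`, `tracks` (list of [coverage_track()]s) and
#'   `expected_tiers`.
#' @export
make_qc_cohort <- function(n_samples = 288L,
                           cumulative_counts = c(225L, 264L, 281L),
                           policy = qc_policy(), panel_bases = 2000L,
                           seed = 1L) {
  if (n_samples <= 0) stopf("nbsval_bad_config", "n_samples must be > 0")
  cc <- as.integer(cumulative_counts)
  if (length(cc) != 3 || any(diff(cc) < 0) || cc[3] > n_samples) {
    stopf("nbsval_bad_config",
          "cumulative_counts must be non-decreasing and <= n_samples")
  }
  panel <- build_panel(genomic_intervals("qcpanel", 0L, panel_bases),
                       padding_bp = 0L, name = "qc")
  N <- panel_total_bases(panel)
  cuts <- ceiling(policy$tier_cutoffs * N)  # min bases for each tier
  n_per_tier <- c(n_samples - cc[3], cc[3] - cc[2], cc[2] - cc[1], cc[1])
  ranges <- list(c(0L, cuts[1] - 1L), c(cuts[1], cuts[2] - 1L),
                 c(cuts[2], cuts[3] - 1L), c(cuts[3], N))
  local_seed(seed, {
    tiers <- rep(qc_tiers, times = n_per_tier)
    tracks <- lapply(seq_len(n_samples), function(i) {
      rg <- ranges[[match(tiers[i], qc_tiers)]]
      k <- sample(seq.int(rg[1], rg[2]), 1L)
      covered <- sample(N, k)
      depth <- rep(policy$depth_threshold %/% 3L, N)
      depth[covered] <- policy$depth_threshold + 10L
      coverage_track(panel$contig[1], seq.int(0L, N - 1L), depth,
                     sample_id = sprintf("QC%03d", i))
    })
    list(panel = panel, tracks = tracks, expected_tiers = tiers)
  })
}

# equivalent denormalized representation: prepend the preceding
# reference base to both alleles (used when emitting FP records so the
# in-pipeline normalizer is exercised on real files)
denormalize_variant <- function(contig, pos, ref_allele, alt_allele, ref) {
  if (pos <= 1L) {
    return(list(pos = pos, ref = ref_allele, alt = alt_allele))
  }
  b <- ref_base(ref, contig, pos - 1L)
  list(pos = pos - 1L, ref = paste0(b, ref_allele),
       alt = paste0(b, alt_allele))
}

#' Write a simulated cohort to disk
#'
#' Emits `reference.fasta`, `panel.bed`, `exons.bed`, `str_regions.bed`,
#' `truth.vcf`, one VCF and one per-base depth TSV per sample, a pair
#' manifest and the ground-truth ledger as JSON. All outputs are plain
#' text and byte-identical across reruns of the same configuration.
#' False-positive records are written in an equivalent denormalized
#' representation (shared leading base) so that reading the files back
#' exercises the normalizer.
#'
#' @param sim a [make_truth_and_calls()] result.
#' @param refinfo the matching [make_reference()] result.
#' @param panel the matching panel.
#' @param dir output directory (created if needed).
#' @param denormalize_fp write FPs denormalized (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, refinfo, panel, dir, denormalize_fp = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_fasta(refinfo$ref, fp("reference.fasta"))
  write_bed(panel, fp("panel.bed"))
  write_bed(refinfo$exons, fp("exons.bed"))
  write_bed(refinfo$str_regions, fp("str_regions.bed"))
  write_vcf(sim$truth, fp("truth.vcf"), ref = refinfo$ref,
            sample_id = "TRUTH")
  for (sid in names(sim$samples)) {
    calls <- sim$samples[[sid]]
    if (denormalize_fp) {
      fp_keys <- sim$ledger$samples[[sid]]$fp
      for (r in which(variant_key(calls) %in% fp_keys)) {
        dv <- denormalize_variant(calls$contig[r], calls$pos[r],
                                  calls$ref[r], calls$alt[r], refinfo$ref)
        calls$pos[r] <- dv$pos; calls$ref[r] <- dv$ref; calls$alt[r] <- dv$alt
      }
    }
    write_vcf(calls, fp(paste0(sid, ".vcf")), ref = refinfo$ref,
              sample_id = sid)
    write_depth_tsv(sim$depths[[sid]], fp(paste0(sid, ".depth.tsv")))
  }
  write.table(sim$pairs, fp("pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$ledger, fp("ledger.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
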