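# Config-driven entry points tying the stages together: truth-set
# validation, paired concordance, coverage QC and the ops report. The
# fixed stage order is read -> decompose -> normalize -> filter ->
# restrict -> compare -> report; filtering precedes panel restriction
# (caller-then-intersect), switchable via `filter_before_restrict`.

#' Load a pipeline configuration
#'
#' Reads a YAML configuration (or accepts an equivalent named list) and
#' fills in defaults for the thresholds, policies and ops parameters.
#' Referenced paths are resolved relative to the config file's directory.
#'
#' @param config path to a YAML file, or a named list.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  base_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) {
      stopf("nbsval_bad_config", "config file '%s' not found", config)
    }
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else ifelse(grepl("^(/|~)", p), p, file.path(base_dir, p))
  }
  for (f in c("reference", "panel_bed", "truth_vcf", "str_bed", "out_dir")) {
    config[[f]] <- resolve(config[[f]])
  }
  if (!is.null(config$samples)) {
    config$samples <- lapply(config$samples, function(s) {
      s$vcf <- resolve(s$vcf); s$depth <- resolve(s$depth); s
    })
  }
  config$thresholds <- do.call(filter_thresholds,
                               config$thresholds %||% list())
  config$concordance <- do.call(concordance_policy,
                                config$concordance %||% list())
  config$qc <- do.call(qc_policy, config$qc %||% list())
  config$ops <- do.call(ops_params, config$ops %||% list())
  config$filter_before_restrict <- config$filter_before_restrict %||% TRUE
  structure(config, class = "pipeline_config")
}

check_paths <- function(paths) {
  for (p in paths) {
    if (!is.null(p) && !file.exists(p)) {
      stopf("nbsval_bad_config", "input file '%s' not found", p)
    }
  }
}

stage_log <- function(stage, n_in, n_out, quiet) {
  if (!quiet) {
    message(sprintf("[nbsval] %-10s in=%d out=%d", stage, n_in, n_out))
  }
}

# shared per-sample preparation: read, decompose, normalize, filter,
# restrict (order per config)
prepare_calls <- function(vcf_path, ref, panel, config, quiet = TRUE) {
  raw <- read_vcf(vcf_path)
  dec <- decompose(raw)
  stage_log("decompose", nrow(raw), nrow(dec), quiet)
  nrm <- normalize_calls(dec, ref)
  stage_log("normalize", nrow(dec), nrow(nrm), quiet)
  do_filter <- function(v) {
    fr <- filter_calls(v, config$thresholds, ref)
    stage_log("filter", nrow(v), nrow(fr$passed), quiet)
    fr
  }
  if (isTRUE(config$filter_before_restrict)) {
    fr <- do_filter(nrm)
    kept <- restrict_calls(fr$passed, panel)
    stage_log("restrict", nrow(fr$passed), nrow(kept), quiet)
  } else {
    res <- restrict_calls(nrm, panel)
    stage_log("restrict", nrow(nrm), nrow(res), quiet)
    fr <- do_filter(res)
    kept <- fr$passed
  }
  list(calls = kept, rejected = fr$rejected)
}

#' Run the truth-set validation analysis
#'
#' Reads the query VCF(s) and the truth VCF, runs each through the fixed
#' stage order, compares against the truth set over the panel, and writes
#' a JSON + TSV validation report (plus optional FP/FN VCF partitions).
#'
#' @param config a [pipeline_config()] (or path/list coercible to one).
#' @param quiet suppress stage logging.
#' @return the [validation_report()], invisibly.
#' @export
run_validate <- function(config, quiet = FALSE) {
  config <- as_pipeline_config(config)
  check_paths(c(config$reference, config$panel_bed, config$truth_vcf,
                lapply(config$samples, `[[`, "vcf")))
  ref <- read_fasta(config$reference)
  panel_iv <- read_bed(config$panel_bed)
  panel <- build_panel(panel_iv, padding_bp = 0L, name = "panel")
  truth <- restrict_calls(read_calls(config$truth_vcf, ref), panel)
  str_regions <- if (!is.null(config$str_bed)) read_bed(config$str_bed)
                 else genomic_intervals()
  comparisons <- lapply(config$samples, function(s) {
    prep <- prepare_calls(s$vcf, ref, panel, config, quiet)
    compare_to_truth(prep$calls, truth, panel)
  })
  report <- validation_report(comparisons, ref = ref,
                              str_regions = str_regions)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(config$out_dir, "validation_report")
    jsonlite::write_json(list(
      schema = "nbsval/validation/v1",
      confusion = report$confusion[c("tp", "fp", "fn", "tn")],
      sensitivity_pct = report$sensitivity,
      specificity_pct = report$specificity,
      mcc = report$mcc,
      unique_matching_variants = report$unique_matching_variants
    ), paste0(out, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(report$per_sample, paste0(out, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    fp_all <- report$fp_breakdown
    write_vcf(fp_all[, setdiff(names(fp_all), c("in_STR", "in_homopolymer")),
                     drop = FALSE],
              file.path(config$out_dir, "false_positives.vcf"), ref = ref)
    fn_all <- do.call(rbind, c(list(empty_variants()),
                               lapply(comparisons, attr, "fn_calls")))
    write_vcf(fn_all, file.path(config$out_dir, "false_negatives.vcf"),
              ref = ref)
  }
  invisible(report)
}

#' Run the paired-sample concordance analysis
#'
#' For every configured pair, prepares both members' call sets, compares
#' them with [compare_pair()] under the configured policy, and summarises
#' the cohort. Writes per-pair JSON, a cohort TSV and the all-regions vs
#' high-coverage summary table.
#'
#' @inheritParams run_validate
#' @return the [cohort_concordance()] summary, invisibly.
#' @export
run_concord <- function(config, quiet = FALSE) {
  config <- as_pipeline_config(config)
  if (is.null(config$pairs) || length(config$pairs) == 0) {
    stopf("nbsval_bad_config", "no pairs configured")
  }
  for (pr in config$pairs) {
    if (!all(unlist(pr) %in% names(config$samples))) {
      stopf("nbsval_bad_config",
            "pair references sample(s) missing from the manifest: %s",
            paste(unlist(pr), collapse = ", "))
    }
  }
  check_paths(c(config$reference, config$panel_bed,
                lapply(config$samples, `[[`, "vcf"),
                lapply(config$samples, `[[`, "depth")))
  ref <- read_fasta(config$reference)
  panel <- build_panel(read_bed(config$panel_bed), padding_bp = 0L)
  prepped <- lapply(config$samples, function(s) {
    prepare_calls(s$vcf, ref, panel, config, quiet)$calls
  })
  tracks <- lapply(config$samples, function(s) read_depth_tsv(s$depth))
  pairs <- lapply(config$pairs, function(pr) {
    a <- pr[[1]]; b <- pr[[2]]
    compare_pair(prepped[[a]], prepped[[b]], tracks[[a]], tracks[[b]],
                 policy = config$concordance, name_A = a, name_B = b)
  })
  cohort <- cohort_concordance(pairs)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      schema = "nbsval/concordance/v1",
      n_pairs = cohort$n_pairs,
      mean_concordance_all_pct = cohort$mean_concordance_all_pct,
      mean_concordance_high_cov_pct = cohort$mean_concordance_high_cov_pct,
      n_calls_total = cohort$n_calls_total,
      n_calls_union = cohort$n_calls_union,
      n_concordant_unique = cohort$n_concordant_unique,
      per_category_counts = cohort$per_category_counts
    ), file.path(config$out_dir, "concordance_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(cohort$per_pair,
                file.path(config$out_dir, "concordance_per_pair.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(concordance_summary_table(pairs),
                file.path(config$out_dir, "concordance_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(cohort)
}

#' Run the coverage QC analysis
#'
#' @inheritParams run_validate
#' @return the [run_summary()] object, invisibly.
#' @export
run_coverage_qc <- function(config, quiet = FALSE) {
  config <- as_pipeline_config(config)
  check_paths(c(config$reference, config$panel_bed,
                lapply(config$samples, `[[`, "depth")))
  panel <- build_panel(read_bed(config$panel_bed), padding_bp = 0L)
  qcs <- lapply(names(config$samples), function(sid) {
    track <- read_depth_tsv(config$samples[[sid]]$depth)
    q <- sample_qc(track, panel, config$qc)
    q$sample_id <- sid
    q
  })
  summary <- run_summary(qcs, config$qc)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    per_sample <- data.frame(
      sample = vapply(qcs, `[[`, character(1), "sample_id"),
      pct_bases_at_depth = vapply(qcs, `[[`, numeric(1),
                                  "pct_bases_at_depth"),
      tier = vapply(qcs, `[[`, character(1), "tier"))
    write.table(per_sample, file.path(config$out_dir, "coverage_qc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      schema = "nbsval/coverage_qc/v1",
      n_samples = summary$n_samples,
      cumulative = summary$cumulative,
      tier_counts = as.list(summary$tier_counts)
    ), file.path(config$out_dir, "coverage_qc.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}

#' Run the laboratory operations report
#'
#' @inheritParams run_validate
#' @return the [ops_report()], invisibly.
#' @export
run_ops <- function(config, quiet = FALSE) {
  config <- as_pipeline_config(config)
  schedule <- if (!is.null(config$schedule)) {
    stage_schedule(vapply(config$schedule, `[[`, character(1), "stage"),
                   vapply(config$schedule, function(x) as.integer(x$day),
                          integer(1)))
  } else stage_schedule()
  costs <- if (!is.null(config$costs)) {
    do.call(cost_params, config$costs)
  } else NULL
  report <- ops_report(schedule, config$ops, costs)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(c(list(schema = "nbsval/ops/v1"), unclass(report)),
                         file.path(config$out_dir, "ops_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!quiet) print(report)
  invisible(report)
}

#' Generate a full synthetic cohort from a config
#'
#' Drives the generator end-to-end: reference and repeat tracts, padded
#' panel, truth set, paired call sets, depth tracks, and the ground-truth
#' ledger, written to `out_dir`.
#'
#' @param sim_args list of [sim_config()] arguments (e.g. `list(seed = 7)`).
#' @param out_dir output directory.
#' @return list with the in-memory `refinfo`, `panel` and `sim` objects,
#'   invisibly.
#' @export
simulate_cohort <- function(sim_args = list(), out_dir = NULL) {
  cfg <- do.call(sim_config, sim_args)
  refinfo <- make_reference(cfg)
  panel <- build_panel(refinfo$exons, padding_bp = cfg$panel_padding,
                       name = "synthetic-panel")
  sim <- make_truth_and_calls(cfg, refinfo, panel)
  if (!is.null(out_dir)) write_cohort(sim, refinfo, panel, out_dir)
  invisible(list(cfg = cfg, refinfo = refinfo, panel = panel, sim = sim))
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) config else pipeline_config(config)
}
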