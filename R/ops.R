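#' Laboratory stage schedule
#'
#' Ordered assignment of pipeline stages to working days. The default is
#' the four-day bloodspot sequencing workflow: booking-on, punching, DNA
#' extraction and the start of library preparation on day 1; enzymatic
#' digestion, barcoding, library QC, pooling and chip loading on day 2;
#' sequencing and data processing on day 3; analysis and reporting on
#' day 4.
#'
#' @param stages character vector of stage names, in execution order.
#' @param days integer day index (>= 1) per stage, non-decreasing.
#' @return a `stage_schedule` data.frame.
#' @export
stage_schedule <- function(stages = NULL, days = NULL) {
  if (is.null(stages)) {
    stages <- c("booking_on", "dbs_punching", "dna_extraction",
                "library_prep_start",
                "fupa_digestion", "barcode_ligation", "library_qc",
                "library_pooling", "chip_loading",
                "sequencing", "data_processing",
                "data_analysis", "reporting")
    days <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 4L, 4L)
  }
  days <- as.integer(days)
  if (length(stages) == 0 || length(stages) != length(days)) {
    stopf("nbsval_bad_config", "schedule needs matching nonempty stages/days")
  }
  if (any(days < 1L) || any(diff(days) < 0L)) {
    stopf("nbsval_bad_config",
          "day indices must be >= 1 and non-decreasing in stage order")
  }
  structure(data.frame(stage = stages, day = days, stringsAsFactors = FALSE),
            class = c("stage_schedule", "data.frame"))
}

#' Turnaround time of a schedule
#'
#' `turnaround_days` is the number of calendar days spanned by the
#' schedule (last day minus first day plus one). A sample needing repeat
#' testing goes through two sequential full cycles, so
#' `repeat_turnaround_days` is twice that.
#'
#' @param s a [stage_schedule()].
#' @return integer number of days.
#' @examples
#' turnaround_days(stage_schedule())         # 4
#' repeat_turnaround_days(stage_schedule())  # 8
#' @export
turnaround_days <- function(s) {
  if (nrow(s) == 0) stopf("nbsval_bad_config", "empty schedule")
  as.integer(max(s$day) - min(s$day) + 1L)
}

#' @rdname turnaround_days
#' @export
repeat_turnaround_days <- function(s) {
  2L * turnaround_days(s)
}

#' Batch throughput parameters
#'
#' Defaults describe the reference configuration: two 96-library runs
#' prepared per day on one sequencer, seven days a week, with 3 of every
#' 96 samples requiring a repeat pass.
#'
#' @param samples_per_run libraries per sequencing run (default 96).
#' @param runs_per_day runs set up per day per sequencer (default 2).
#' @param days_per_week operating days (default 7).
#' @param repeat_rate fraction of samples repeated, in `[0, 1)`
#'   (default 3/96).
#' @param sequencers number of sequencers (default 1).
#' @return an `ops_params` list.
#' @export
ops_params <- function(samples_per_run = 96L, runs_per_day = 2L,
                       days_per_week = 7L, repeat_rate = 3 / 96,
                       sequencers = 1L) {
  p <- list(samples_per_run = as.integer(samples_per_run),
            runs_per_day = as.integer(runs_per_day),
            days_per_week = as.integer(days_per_week),
            repeat_rate = as.numeric(repeat_rate),
            sequencers = as.integer(sequencers))
  if (p$samples_per_run <= 0 || p$runs_per_day <= 0 ||
      p$days_per_week <= 0 || p$sequencers <= 0 ||
      p$repeat_rate < 0 || p$repeat_rate >= 1) {
    stopf("nbsval_bad_config",
          "ops parameters must be positive with repeat_rate in [0,1)")
  }
  structure(p, class = "ops_params")
}

#' Weekly sample throughput
#'
#' Gross throughput is `samples_per_run * runs_per_day * days_per_week *
#' sequencers` library slots per week; because a fraction `repeat_rate`
#' of slots is consumed by repeat testing, the net number of unique
#' samples processed is `floor(gross * (1 - repeat_rate))`.
#'
#' @param p an [ops_params()] object.
#' @return list with `gross` and `net_unique` integer counts.
#' @examples
#' weekly_throughput(ops_params())  # gross 1344, net 1302
#' @export
weekly_throughput <- function(p) {
  gross <- p$samples_per_run * p$runs_per_day * p$days_per_week * p$sequencers
  list(gross = as.integer(gross),
       net_unique = as.integer(floor(gross * (1 - p$repeat_rate))))
}

#' @rdname weekly_throughput
#' @export
daily_library_capacity <- function(p) {
  as.integer(p$samples_per_run * p$runs_per_day * p$sequencers)
}

#' Itemized per-sample cost components
#'
#' Cost components are user-supplied currency amounts per sample; the
#' model only guarantees the aggregation arithmetic. Items flagged
#' repeat-sensitive are inflated by `1 / (1 - repeat_rate)`, since the
#' repeated fraction of samples consumes those items twice on average.
#'
#' @param items named numeric vector of per-sample costs (>= 0), e.g.
#'   `c(consumables = ..., equipment = ..., labour = ...)`.
#' @param repeat_sensitive names of items subject to repeat inflation.
#' @param labour_items names of items dropped when labour is excluded.
#' @return a `cost_params` list.
#' @export
cost_params <- function(items, repeat_sensitive = names(items),
                        labour_items = intersect("labour", names(items))) {
  if (length(items) == 0 || is.null(names(items)) || any(items < 0)) {
    stopf("nbsval_bad_config", "items must be a named vector of costs >= 0")
  }
  stopifnot(all(repeat_sensitive %in% names(items)),
            all(labour_items %in% names(items)))
  structure(list(items = items, repeat_sensitive = repeat_sensitive,
                 labour_items = labour_items),
            class = "cost_params")
}

#' Aggregate cost per sample
#'
#' @param c a [cost_params()] object.
#' @param p an [ops_params()] object (supplies the repeat rate).
#' @param include_labour include labour items (default TRUE).
#' @return cost per sample in the items' currency units.
#' @examples
#' cp <- cost_params(c(reagents = 10), repeat_sensitive = "reagents")
#' cost_per_sample(cp, ops_params())  # 10 * 96/93 = 10.32
#' @export
cost_per_sample <- function(c, p, include_labour = TRUE) {
  items <- c$items
  if (!include_labour && length(c$labour_items)) {
    items <- items[setdiff(names(items), c$labour_items)]
  }
  infl <- ifelse(names(items) %in% c$repeat_sensitive,
                 1 / (1 - p$repeat_rate), 1)
  sum(items * infl)
}

#' Full operations report
#'
#' @param schedule a [stage_schedule()].
#' @param params an [ops_params()] object.
#' @param costs optional [cost_params()] object.
#' @return an `ops_report` list of turnaround, throughput and cost figures.
#' @export
ops_report <- function(schedule = stage_schedule(), params = ops_params(),
                       costs = NULL) {
  tp <- weekly_throughput(params)
  out <- list(
    turnaround_days = turnaround_days(schedule),
    repeat_turnaround_days = repeat_turnaround_days(schedule),
    daily_library_capacity = daily_library_capacity(params),
    weekly_gross = tp$gross,
    weekly_net_unique = tp$net_unique
  )
  if (!is.null(costs)) {
    out$cost_per_sample_incl_labour <- cost_per_sample(costs, params, TRUE)
    out$cost_per_sample_excl_labour <- cost_per_sample(costs, params, FALSE)
  }
  structure(out, class = "ops_report")
}

#' @export
print.ops_report <- function(x, ...) {
  cat("Operations report\n")
  cat(sprintf("  turnaround: %d day(s); repeat turnaround: %d day(s)\n",
              x$turnaround_days, x$repeat_turnaround_days))
  cat(sprintf("  daily library capacity: %d; weekly throughput: %d gross / %d net unique\n",
              x$daily_library_capacity, x$weekly_gross, x$weekly_net_unique))
  if (!is.null(x$cost_per_sample_incl_labour)) {
    cat(sprintf("  cost/sample: %.2f (incl labour) / %.2f (excl labour)\n",
                x$cost_per_sample_incl_labour, x$cost_per_sample_excl_labour))
  }
  invisible(x)
}
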