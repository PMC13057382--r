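# End-to-end pipeline: simulate -> segment -> classify -> summarize ->
# analyze, with a run-in exclusion, a ground-truth-vs-detected confusion
# table and a machine-readable report.

.pipeline_config_keys <- c("seed", "cohort", "classifier", "run_in_frac",
                           "out_dir", "write_waveforms", "verbose")
.cohort_config_keys <- c("n_patients", "duration_s", "arm_effect",
                         "cough_rate_per_min", "waveforms")

#' Validate a pipeline run configuration
#'
#' Checks the configuration (a named list, or a YAML file path) against the
#' known schema; unknown keys are rejected before any work is done.
#'
#' @param config Named list or path to a YAML file with blocks `seed`,
#'   `cohort` (`n_patients`, `duration_s`, ...), `classifier` (threshold
#'   overrides for [classifier_config()]), `run_in_frac`, `out_dir`,
#'   `write_waveforms`, `verbose`.
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .pipeline_config_keys)
  if (length(unknown))
    stop("validate_run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$cohort)) {
    unknown <- setdiff(names(config$cohort), .cohort_config_keys)
    if (length(unknown))
      stop("validate_run_config: unknown cohort key(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(config$classifier)) {
    unknown <- setdiff(names(config$classifier),
                       names(formals(classifier_config)))
    if (length(unknown))
      stop("validate_run_config: unknown classifier key(s): ",
           paste(unknown, collapse = ", "))
  }
  defaults <- list(seed = 1, run_in_frac = 1 / 3, out_dir = NULL,
                   write_waveforms = FALSE, verbose = FALSE,
                   cohort = list(n_patients = 8, duration_s = 600),
                   classifier = list())
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$run_in_frac >= 0, cfg$run_in_frac < 1,
            cfg$cohort$n_patients >= 2, cfg$cohort$duration_s >= 60)
  cfg
}

#' Trim the leading run-in phase from a record
#'
#' Drops the first `from_s` seconds of every channel; times in downstream
#' results are relative to the trimmed start.
#'
#' @param record A [waveform_record()].
#' @param from_s Seconds to drop from the start.
#' @return The trimmed record.
#' @export
trim_record <- function(record, from_s) {
  if (from_s <= 0) return(record)
  rate <- record$sample_rate_hz
  i0 <- as.integer(floor(from_s * rate)) + 1L
  n <- length(record$paw)
  if (i0 >= n - 1L) stop("trim_record: nothing left after trimming")
  idx <- i0:n
  sub <- function(x) if (is.null(x)) NULL else x[idx]
  waveform_record(paw = sub(record$paw), flow = sub(record$flow),
                  sample_rate_hz = rate, t0_s = 0,
                  volume = sub(record$volume), pes = sub(record$pes),
                  etco2 = sub(record$etco2), spo2 = sub(record$spo2),
                  artifact_mask = sub(record$artifact_mask),
                  meta = record$meta)
}

# Greedy per-type matching of truth events to detected events within a time
# tolerance; returns confusion counts.
confusion_counts <- function(truth_times, detected_times, tol_s = 0.35) {
  used <- logical(length(detected_times))
  tp <- 0L
  for (t in truth_times) {
    d <- abs(detected_times - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fn = length(truth_times) - tp,
    fp = length(detected_times) - tp)
}

# Analyze one simulated session: run-in trim, mask, segment, classify,
# summarize, and score against ground truth on the unmasked measurement
# window. Returns summary row, truth row (mask-consistent) and confusion.
analyze_session <- function(session, cut_s, cls_cfg) {
  rec <- trim_record(session$record, cut_s)
  res <- classify_record(rec, cls_cfg)
  summ <- summarize_period(res$record, res$events, res$breaths,
                           comfort_b = session$comfort_b)

  # ground truth restricted to the measurement window and to unmasked time
  truth <- session$truth
  truth <- truth[truth$time_s >= cut_s, , drop = FALSE]
  truth$time_s <- truth$time_s - cut_s
  mask <- res$record$artifact_mask
  rate <- res$record$sample_rate_hz
  t_masked <- function(tv) {
    idx <- pmin(pmax(as.integer(round(tv * rate)) + 1L, 1L), length(mask))
    mask[idx]
  }
  # truth machine breaths masked by fractional overlap of their cycle (the
  # same 10 percent rule the detector applies to breath segments)
  mt <- session$machine_times
  n_machine_truth <- 0L
  breath_masked <- logical(0)
  trig <- numeric(0)
  if (!is.null(mt)) {
    keep <- mt[, 1L] >= cut_s
    mt <- mt[keep, , drop = FALSE] - cut_s
    trig <- mt[, 1L]
    bounds <- c(trig, record_duration(res$record))
    breath_masked <- vapply(seq_along(trig), function(k) {
      a <- max(1L, as.integer(round(bounds[k] * rate)) + 1L)
      b <- min(length(mask), as.integer(round(bounds[k + 1L] * rate)) + 1L)
      mean(mask[a:b]) > 0.1
    }, logical(1))
    n_machine_truth <- sum(!breath_masked)
  }
  truth_events <- truth[truth$kind %in% EVENT_TYPES, , drop = FALSE]
  if (nrow(truth_events)) {
    drop <- t_masked(truth_events$time_s)
    if (length(trig)) {
      bi <- findInterval(truth_events$time_s, trig)
      in_breath <- bi >= 1L & truth_events$kind != "IE"
      drop[in_breath] <- drop[in_breath] | breath_masked[bi[in_breath]]
    }
    truth_events <- truth_events[!drop, , drop = FALSE]
  }
  truth_ai <- if (n_machine_truth + sum(truth_events$kind == "IE") > 0) {
    compute_ai(truth_events$kind, n_machine_truth)
  }
  conf <- lapply(EVENT_TYPES, function(tp) {
    confusion_counts(truth_events$time_s[truth_events$kind == tp],
                     res$events$time_s[res$events$type == tp])
  })
  conf <- data.frame(type = EVENT_TYPES, do.call(rbind, conf))

  list(summary = summ, summary_row = period_summary_row(summ),
       truth_row = if (!is.null(truth_ai)) {
         r <- session_truth_row(session)
         r$ai_pct <- truth_ai$ai_pct
         r$major_ai_pct <- truth_ai$major_ai_pct
         r$minor_ai_pct <- truth_ai$minor_ai_pct
         r
       },
       confusion = conf, events = res$events, breaths = res$breaths)
}

#' Run the full pipeline
#'
#' Simulates a crossover cohort, excludes the leading run-in fraction of
#' each session, segments and classifies the measurement windows, summarizes
#' each period, scores detection against ground truth and runs the paired
#' crossover analysis. Deterministic for a given seed. When `out_dir` is
#' set, intermediates (events, per-session summaries, the analysis table)
#' and a JSON report are written there.
#'
#' @param config See [validate_run_config()].
#' @return An object of class `run_report`: `session_table` (per session:
#'   detected and ground-truth AI family plus secondary outcomes),
#'   `crossover_table` (from [analyze_crossover()]), `confusion`
#'   (per-type tp/fn/fp with sensitivity and precision), `config`, `seed`,
#'   `version`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_run_config(config)
  cls_cfg <- do.call(classifier_config, cfg$classifier)
  co_args <- cfg$cohort
  co_call <- list(n_patients = co_args$n_patients,
                  duration_s = co_args$duration_s,
                  seed = cfg$seed,
                  cough_rate_per_min = co_args$cough_rate_per_min %||% 0.2,
                  waveforms = TRUE)
  if (!is.null(co_args$arm_effect)) {
    co_call$arm_effect <- unlist(co_args$arm_effect)
  }
  cohort <- do.call(generate_crossover_cohort, co_call)
  cut_s <- cfg$run_in_frac * cfg$cohort$duration_s

  session_rows <- list()
  conf_all <- NULL
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    for (arm in c("conventional", "closed_loop")) {
      if (isTRUE(cfg$verbose))
        message("analyzing ", p$patient_id, " / ", arm)
      sa <- analyze_session(p[[arm]], cut_s, cls_cfg)
      id_cols <- data.frame(patient_id = p$patient_id, arm = arm,
                            stringsAsFactors = FALSE)
      det <- cbind(id_cols, sa$summary_row)
      names(sa$truth_row) <- paste0("truth_", names(sa$truth_row))
      session_rows[[length(session_rows) + 1L]] <- cbind(det, sa$truth_row)
      conf_all <- if (is.null(conf_all)) sa$confusion else {
        cbind(type = conf_all$type,
              conf_all[, -1L, drop = FALSE] + sa$confusion[, -1L, drop = FALSE])
      }
      if (!is.null(out_dir)) {
        write_events(sa$events, file.path(out_dir,
          sprintf("%s_%s_events.csv", p$patient_id, arm)))
        if (isTRUE(cfg$write_waveforms)) {
          write_waveform(p[[arm]]$record, file.path(out_dir,
            sprintf("%s_%s_waveform.csv", p$patient_id, arm)))
        }
      }
    }
  }
  session_table <- do.call(rbind, session_rows)
  rownames(session_table) <- NULL
  conf_all$sensitivity <- with(conf_all, ifelse(tp + fn > 0, tp / (tp + fn), NA))
  conf_all$precision <- with(conf_all, ifelse(tp + fp > 0, tp / (tp + fp), NA))
  crossover_table <- analyze_crossover(session_table)

  report <- structure(list(
    session_table = session_table,
    crossover_table = crossover_table,
    confusion = conf_all,
    config = cfg, seed = cfg$seed,
    version = as.character(utils::packageVersion("ventsync"))
  ), class = "run_report")
  if (!is.null(out_dir)) {
    utils::write.csv(session_table, file.path(out_dir, "session_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(crossover_table, file.path(out_dir, "crossover_table.csv"),
                     row.names = FALSE)
    utils::write.csv(conf_all, file.path(out_dir, "confusion.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, version = report$version,
           config = cfg[setdiff(names(cfg), "out_dir")],
           confusion = conf_all,
           crossover = crossover_table),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, %d sessions\n", x$seed,
              nrow(x$session_table)))
  cat("\nDetection vs ground truth:\n")
  print(x$confusion, row.names = FALSE)
  cat("\nCrossover analysis (closed-loop minus conventional):\n")
  print(x$crossover_table[, c("outcome", "closed_loop", "conventional",
                              "estimate", "ci_low", "ci_high", "p_value",
                              "method")], row.names = FALSE, digits = 3)
  invisible(x)
}
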