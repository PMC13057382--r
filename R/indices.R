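# Per-period outcome computation: the Asynchrony Index family and the
# secondary physiological summaries.

#' Asynchrony Index computation
#'
#' The Asynchrony Index (AI) is the percentage of asynchronous events over
#' the number of machine breaths plus ineffective efforts:
#' `AI = 100 * (major + minor events) / (machine breaths + IE)`. The Major
#' AI uses only auto-triggering, double breaths and ineffective efforts in
#' the numerator; the Minor AI uses trigger delay, early cycling and late
#' cycling. All three share the same denominator, so
#' `AI = Major AI + Minor AI` exactly.
#'
#' @param events An event data frame (as from [classify_session()]) with a
#'   `type` column, or a character vector of event types.
#' @param n_machine_breaths Number of machine breaths in the period.
#' @return An object of class `ai_result`: counts per type
#'   (`n_at`, `n_db`, `n_ie`, `n_td`, `n_ec`, `n_lc`), `n_machine_breaths`,
#'   `denominator`, and `ai_pct`, `major_ai_pct`, `minor_ai_pct`.
#' @examples
#' ev <- rep(c("IE", "AT", "DB", "TD", "EC"), c(10, 5, 5, 10, 5))
#' compute_ai(ev, n_machine_breaths = 90)  # AI 35, major 20, minor 15
#' @export
compute_ai <- function(events, n_machine_breaths) {
  types <- if (is.data.frame(events)) events$type else as.character(events)
  if (length(types) && !all(types %in% EVENT_TYPES))
    stop("compute_ai: unknown event type(s): ",
         paste(setdiff(unique(types), EVENT_TYPES), collapse = ", "))
  cnt <- vapply(EVENT_TYPES, function(tp) sum(types == tp), integer(1))
  denom <- n_machine_breaths + cnt[["IE"]]
  if (denom <= 0)
    stop("compute_ai: zero denominator (no machine breaths and no IE)")
  major <- cnt[["AT"]] + cnt[["DB"]] + cnt[["IE"]]
  minor <- cnt[["TD"]] + cnt[["EC"]] + cnt[["LC"]]
  major_pct <- 100 * major / denom
  minor_pct <- 100 * minor / denom
  structure(list(
    n_machine_breaths = as.integer(n_machine_breaths),
    n_at = cnt[["AT"]], n_db = cnt[["DB"]], n_ie = cnt[["IE"]],
    n_td = cnt[["TD"]], n_ec = cnt[["EC"]], n_lc = cnt[["LC"]],
    denominator = as.integer(denom),
    # summed so that AI = Major + Minor holds to the last bit
    ai_pct = major_pct + minor_pct,
    major_ai_pct = major_pct,
    minor_ai_pct = minor_pct
  ), class = "ai_result")
}

#' @export
print.ai_result <- function(x, ...) {
  cat(sprintf("<ai_result> AI %.1f%% (major %.1f%%, minor %.1f%%)\n",
              x$ai_pct, x$major_ai_pct, x$minor_ai_pct))
  cat(sprintf("  denominator %d = %d machine breaths + %d IE\n",
              x$denominator, x$n_machine_breaths, x$n_ie))
  cat(sprintf("  AT %d  DB %d  IE %d | TD %d  EC %d  LC %d\n",
              x$n_at, x$n_db, x$n_ie, x$n_td, x$n_ec, x$n_lc))
  invisible(x)
}

#' Summarize one measurement period
#'
#' Computes the AI family over the period's events and breaths, plus the
#' secondary outcomes: mean SpO2 and EtCO2 over unmasked samples, mean
#' breath-by-breath leak, and the Comfort-B score with its interpretation
#' band. Masked breaths are excluded from the AI denominator and leak mean;
#' missing channels yield `NA` means rather than zeros.
#'
#' @param record A [waveform_record()].
#' @param events Event data frame from [classify_session()].
#' @param breaths `breath_segments` from [detect_breaths()].
#' @param comfort_b Comfort-B behavioral score (integer 6-30), or `NA`.
#' @return An object of class `period_summary`: the `ai_result` plus
#'   `mean_spo2_pct`, `mean_etco2_mmhg`, `mean_leak_pct`, `comfort_b`,
#'   `comfort_band`, `duration_s`, `n_breaths_masked`.
#' @export
summarize_period <- function(record, events, breaths, comfort_b = NA_integer_) {
  stopifnot(inherits(record, "waveform_record"))
  unmasked <- !record$artifact_mask
  kept <- breaths[!breaths$masked, , drop = FALSE]
  ai <- compute_ai(events, n_machine_breaths = nrow(kept))
  ch_mean <- function(x) {
    if (is.null(x)) NA_real_ else mean(x[unmasked])
  }
  leak <- if (nrow(kept)) {
    ok <- kept$v_insp_ml > 0
    if (any(ok)) mean(compute_breath_leak(kept$v_insp_ml[ok],
                                          kept$v_exp_ml[ok])) else NA_real_
  } else NA_real_
  structure(list(
    ai = ai,
    mean_spo2_pct = ch_mean(record$spo2),
    mean_etco2_mmhg = ch_mean(record$etco2),
    mean_leak_pct = leak,
    comfort_b = comfort_b,
    comfort_band = if (is.na(comfort_b)) NA_character_ else comfort_band(comfort_b),
    duration_s = record_duration(record),
    n_breaths_masked = sum(breaths$masked)
  ), class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("<period_summary> %.1f min\n", x$duration_s / 60))
  print(x$ai)
  cat(sprintf("  leak %.1f%%  SpO2 %.1f%%  EtCO2 %.1f mmHg  Comfort-B %s (%s)\n",
              x$mean_leak_pct, x$mean_spo2_pct, x$mean_etco2_mmhg,
              as.character(x$comfort_b), x$comfort_band %||% "NA"))
  invisible(x)
}

#' Comfort-B score interpretation band
#'
#' Comfort-B behavioral scores range 6-30: below 10 suggests possible
#' over-sedation, 12-17 adequate comfort, above 17 agitation or inadequate
#' sedation. Scores of 10-11 fall in an unnamed gap between the published
#' bands and are reported as `indeterminate`.
#'
#' @param score Integer score(s) between 6 and 30 (vectorized).
#' @return Character vector in `c("over_sedation", "indeterminate",
#'   "adequate", "agitation")`.
#' @examples
#' comfort_band(c(8, 11, 14, 18))
#' @export
comfort_band <- function(score) {
  if (any(score < 6 | score > 30))
    stop("comfort_band: score must be between 6 and 30")
  ifelse(score < 10, "over_sedation",
         ifelse(score < 12, "indeterminate",
                ifelse(score <= 17, "adequate", "agitation")))
}

# One flat row of outcome values for the crossover analysis table.
period_summary_row <- function(ps) {
  ai <- ps$ai
  data.frame(
    ai_pct = ai$ai_pct, major_ai_pct = ai$major_ai_pct,
    minor_ai_pct = ai$minor_ai_pct,
    db_pct = 100 * ai$n_db / ai$denominator,
    at_pct = 100 * ai$n_at / ai$denominator,
    ie_pct = 100 * ai$n_ie / ai$denominator,
    td_pct = 100 * ai$n_td / ai$denominator,
    ec_pct = 100 * ai$n_ec / ai$denominator,
    lc_pct = 100 * ai$n_lc / ai$denominator,
    comfort_b = as.numeric(ps$comfort_b),
    etco2_mmhg = ps$mean_etco2_mmhg,
    spo2_pct = ps$mean_spo2_pct,
    leak_pct = ps$mean_leak_pct
  )
}
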