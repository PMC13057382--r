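# Breath-by-breath asynchrony classification.
#
# Event taxonomy: major asynchronies are auto-triggering (AT), double breath
# (DB) and ineffective effort (IE); minor asynchronies are trigger delay
# (TD), early cycling (EC) and late cycling (LC). Precedence: AT and TD are
# mutually exclusive (AT requires the absence of an effort, TD requires
# one); DB attaches to the second cycle of its pair and suppresses an EC
# call on the first (early cycling against a continuing effort is the usual
# double-breath mechanism); an effort already counted as IE is never also
# counted as TD; events inside artifact-masked windows are dropped from
# numerator and denominator alike.

EVENT_TYPES <- c("AT", "DB", "IE", "TD", "EC", "LC")
MAJOR_TYPES <- c("AT", "DB", "IE")
MINOR_TYPES <- c("TD", "EC", "LC")

event_severity <- function(type) {
  ifelse(type %in% MAJOR_TYPES, "major",
         ifelse(type %in% MINOR_TYPES, "minor", NA_character_))
}

empty_events <- function() {
  data.frame(time_s = numeric(0), breath_index = integer(0),
             type = character(0), severity = character(0),
             metric_value = numeric(0), metric_units = character(0),
             stringsAsFactors = FALSE)
}

make_event <- function(time_s, type, breath_index = NA_integer_,
                       metric_value = NA_real_, metric_units = NA_character_) {
  data.frame(time_s = time_s, breath_index = as.integer(breath_index),
             type = type, severity = event_severity(type),
             metric_value = metric_value, metric_units = metric_units,
             stringsAsFactors = FALSE)
}

#' Classify ventilator trigger timing
#'
#' Bins a ventilator response time (effort onset to breath onset) into the
#' standard categories: 0-117 ms normal, 118-234 ms trigger delay (TD),
#' above 234 ms ineffective effort (IE). On continuous time the printed bins
#' are realized as the half-open intervals `(0, 117]`, `(117, 234]`,
#' `(234, Inf)` ms (boundaries configurable).
#'
#' @param response_time_ms Non-negative response time(s) in ms (vectorized).
#' @param cfg A [classifier_config()].
#' @return Character vector in `c("normal", "TD", "IE")`.
#' @examples
#' classify_trigger_timing(c(60, 150, 235))
#' @export
classify_trigger_timing <- function(response_time_ms, cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  if (any(response_time_ms < 0))
    stop("classify_trigger_timing: response time must be non-negative")
  ifelse(response_time_ms <= cfg$normal_trigger_max_ms, "normal",
         ifelse(response_time_ms <= cfg$td_max_ms, "TD", "IE"))
}

# Expiratory-flow deviation regions: samples where flow deviates toward zero
# above the fitted passive envelope. Shared by flow-only IE and EC detection.
# Returns a data frame of candidate notches (time of max deviation, value).
expiratory_deviations <- function(record, breath, cfg) {
  rate <- record$sample_rate_hz
  n <- length(record$flow)
  flow_s <- moving_average(record$flow, 3L)
  ci <- max(1L, as.integer(round(breath$cycle_time_s * rate)) + 1L)
  ei <- min(n, as.integer(round(breath$end_time_s * rate)) + 1L)
  if (ei - ci < as.integer(0.2 * rate)) return(NULL)
  w <- ci:ei
  pef <- w[which.min(flow_s[w])]
  if (ei - pef < 10L) return(NULL)
  dw <- pef:ei
  full_fit <- fit_passive_decay(flow_s[dw], rate, cfg)
  if (full_fit$is_passive) return(NULL)
  # envelope from the early decay limb
  head_n <- min(length(dw), max(8L, as.integer(0.25 * rate)))
  hw <- dw[seq_len(head_n)]
  neg <- which(flow_s[hw] < -cfg$decay_floor_lpm)
  if (length(neg) < 5L) return(NULL)
  tt <- (hw[neg] - 1L) / rate
  fit <- fast_lsq(tt, log(-flow_s[hw[neg]]))
  if (!is.finite(fit$slope) || fit$slope >= 0) return(NULL)
  t_all <- (dw - 1L) / rate
  env <- -exp(fit$intercept + fit$slope * t_all)
  dev <- flow_s[dw] - env  # > 0 means toward zero relative to passive decay
  hits <- dev > cfg$ie_flow_dev_lpm & env < -0.5 * cfg$decay_floor_lpm
  if (!any(hits)) return(NULL)
  runs <- true_runs(hits)
  out <- lapply(seq_len(nrow(runs)), function(r) {
    seg <- runs[r, 1L]:runs[r, 2L]
    k <- seg[which.max(dev[seg])]
    c(time = t_all[k], dev = dev[k])
  })
  as.data.frame(do.call(rbind, out))
}

#' Flow-only detection of ineffective efforts within one breath
#'
#' Without esophageal pressure, an ineffective effort appears during
#' expiration as a notch or bump of expiratory flow toward zero (a failure
#' of the passive exponential decay) combined with an abrupt drop in airway
#' pressure of at least `cfg$ie_paw_drop_cmh2o` within 150 ms of the flow
#' deviation.
#'
#' @param record A [waveform_record()].
#' @param breath One row of a `breath_segments` data frame.
#' @param cfg A [classifier_config()].
#' @return An event data frame (possibly empty) of IE events.
#' @export
detect_ie_flow <- function(record, breath, cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  devs <- expiratory_deviations(record, breath, cfg)
  if (is.null(devs)) return(empty_events())
  rate <- record$sample_rate_hz
  paw_s <- moving_average(record$paw, 3L)
  n <- length(paw_s)
  ev <- empty_events()
  for (r in seq_len(nrow(devs))) {
    tn <- devs$time[r]
    # notches hard against the cycle transition are cycling errors, not IE
    if (tn - breath$cycle_time_s < 0.25) next
    wi <- max(1L, as.integer(round((tn - 0.15) * rate)) + 1L)
    we <- min(n, as.integer(round((tn + 0.15) * rate)) + 1L)
    bi <- max(1L, as.integer(round((tn - 0.45) * rate)) + 1L)
    be <- max(1L, as.integer(round((tn - 0.2) * rate)) + 1L)
    ref <- stats::median(paw_s[bi:be])
    drop <- ref - min(paw_s[wi:we])
    if (drop >= cfg$ie_paw_drop_cmh2o) {
      ev <- rbind(ev, make_event(tn, "IE", metric_value = drop,
                                 metric_units = "cmH2O"))
    }
  }
  ev
}

#' Pes-based detection of ineffective efforts
#'
#' With esophageal pressure available, every effort not followed by a
#' ventilator-triggered breath within the matching window is an ineffective
#' effort, as is every matched effort whose response time exceeds the
#' trigger-delay bound (above 234 ms). Each IE counts once per effort cycle.
#'
#' @param match A `match_result` from [match_efforts()].
#' @param efforts The `effort_events` data frame the match was built from.
#' @param cfg A [classifier_config()].
#' @return An event data frame of IE events (times at effort onsets).
#' @export
detect_ie_pes <- function(match, efforts, cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  ev <- empty_events()
  for (e in match$unmatched_efforts) {
    ev <- rbind(ev, make_event(efforts$onset_time_s[e], "IE",
                               metric_units = "ms"))
  }
  if (nrow(match$links)) {
    late <- match$links[match$links$response_time_ms > cfg$td_max_ms, ,
                        drop = FALSE]
    for (r in seq_len(nrow(late))) {
      ev <- rbind(ev, make_event(efforts$onset_time_s[late$effort_index[r]],
                                 "IE", metric_value = late$response_time_ms[r],
                                 metric_units = "ms"))
    }
  }
  ev[order(ev$time_s), , drop = FALSE]
}

# Pre-onset deflection features for the auto-trigger rule: the maximum
# negative deviation of smoothed Paw below a local pre-window reference, and
# (if Pes is present) the maximum inspiratory deviation of Pes below its
# rolling baseline, both over the pre_onset window before the breath onset.
pre_onset_deflections <- function(record, onset_time_s, cfg,
                                  pes_base = NULL) {
  rate <- record$sample_rate_hz
  n <- length(record$paw)
  paw_s <- moving_average(record$paw, 3L)
  win <- cfg$pre_onset_win_ms / 1000
  a <- max(1L, as.integer(round((onset_time_s - win) * rate)) + 1L)
  b <- max(1L, as.integer(round((onset_time_s - 0.02) * rate)) + 1L)
  # reference from the window itself: an effort dip occupies only its tail,
  # so the median stays near baseline, while pressurization transients from
  # the preceding cycle cannot inflate an external reference
  paw_win <- paw_s[a:min(b, n)]
  paw_dip <- stats::median(paw_win) - min(paw_win)
  pes_dip <- NA_real_
  if (!is.null(record$pes)) {
    if (is.null(pes_base)) pes_base <- pes_baseline(record$pes, rate, cfg)
    pes_s <- moving_average(record$pes, 5L)
    pes_dip <- max(pes_base[a:min(b, n)] - pes_s[a:min(b, n)])
  }
  list(paw_dip = paw_dip, pes_dip = pes_dip)
}

#' Auto-trigger detection for one unmatched breath
#'
#' A machine breath with no linked patient effort is an auto-trigger when
#' there is no preceding negative deflection in airway pressure and (when
#' esophageal pressure is available) no inspiratory Pes deflection in the
#' pre-trigger window: the ventilator inflated without any patient effort.
#'
#' @param record A [waveform_record()].
#' @param breath One row of a `breath_segments` data frame (must be
#'   unmatched).
#' @param cfg A [classifier_config()].
#' @param pes_base Optional precomputed Pes rolling baseline (internal
#'   optimization).
#' @return A one-row AT event data frame, or an empty event frame.
#' @export
detect_auto_trigger <- function(record, breath, cfg = classifier_config(),
                                pes_base = NULL) {
  cfg <- as_classifier_config(cfg)
  f <- pre_onset_deflections(record, breath$onset_time_s, cfg, pes_base)
  effort_paw <- is.finite(f$paw_dip) && f$paw_dip >= cfg$at_paw_dip_cmh2o
  effort_pes <- is.finite(f$pes_dip) && f$pes_dip >= cfg$at_pes_dip_cmh2o
  if (!effort_paw && !effort_pes) {
    make_event(breath$onset_time_s, "AT", metric_value = f$paw_dip,
               metric_units = "cmH2O")
  } else empty_events()
}

#' Double-breath rule for a consecutive breath pair
#'
#' Two consecutive ventilator cycles separated by an expiratory time at or
#' below `db_te_ti_ratio` (default one half) of the first cycle's
#' inspiratory time constitute a double breath; the event attaches to the
#' second cycle. The rule applies regardless of how the first cycle was
#' triggered.
#'
#' @param first,second Consecutive rows of a `breath_segments` data frame
#'   (`second` immediately follows `first`).
#' @param cfg A [classifier_config()].
#' @return A one-row DB event data frame, or an empty event frame.
#' @export
detect_double_breath <- function(first, second, cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  te_gap <- first$end_time_s - first$cycle_time_s
  if (te_gap <= cfg$db_te_ti_ratio * first$ti_s) {
    make_event(second$onset_time_s, "DB",
               metric_value = te_gap / first$ti_s, metric_units = "Te/Ti")
  } else empty_events()
}

#' Cycling-error classification for a matched breath/effort pair
#'
#' The cycling offset is `1000 * (effort termination - breath cycle time)`
#' ms: positive when the ventilator cycled into expiration before the
#' patient's neural inspiration ended. Offsets at or above
#' `cfg$ec_lc_offset_ms` are early cycling (EC); at or below the symmetric
#' negative threshold, late cycling (LC).
#'
#' @param breath One row of a `breath_segments` data frame.
#' @param effort The matched row of an `effort_events` data frame.
#' @param cfg A [classifier_config()].
#' @return A one-row EC/LC event data frame, or an empty event frame.
#' @export
detect_cycling <- function(breath, effort, cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  offset_ms <- 1000 * (effort$termination_time_s - breath$cycle_time_s)
  if (offset_ms >= cfg$ec_lc_offset_ms) {
    make_event(breath$cycle_time_s, "EC", metric_value = offset_ms,
               metric_units = "ms")
  } else if (offset_ms <= -cfg$ec_lc_offset_ms) {
    make_event(breath$cycle_time_s, "LC", metric_value = offset_ms,
               metric_units = "ms")
  } else empty_events()
}

# Flow-only early-cycling fallback: a deviation bump in the first 300 ms of
# expiration (residual inspiratory activity just after the exhalation valve
# opens), without requiring a Paw drop.
detect_ec_flow <- function(record, breath, cfg) {
  devs <- expiratory_deviations(record, breath, cfg)
  if (is.null(devs)) return(empty_events())
  early <- devs[devs$time - breath$cycle_time_s <= 0.3, , drop = FALSE]
  if (!nrow(early)) return(empty_events())
  make_event(breath$cycle_time_s, "EC", metric_value = early$dev[1L],
             metric_units = "L/min")
}

#' Classify a full session
#'
#' Applies the waveform-analysis rules to every machine breath and patient
#' effort of one record and resolves precedence: at most one trigger-phase
#' label (AT or TD) and one cycling-phase label (EC or LC) per machine
#' breath; DB attaches to second cycles and suppresses EC on the first cycle
#' of its pair; IE events live on effort cycles; events in artifact-masked
#' windows are dropped. With Pes present the Pes-based rules take priority
#' over the flow-only morphological fallbacks.
#'
#' @param record A [waveform_record()].
#' @param breaths `breath_segments` from [detect_breaths()].
#' @param efforts `effort_events` from [detect_efforts()], or `NULL` when
#'   Pes is absent.
#' @param match `match_result` from [match_efforts()], or `NULL` when Pes is
#'   absent.
#' @param cfg A [classifier_config()].
#' @return A time-ordered event data frame with columns `time_s`,
#'   `breath_index`, `type`, `severity`, `metric_value`, `metric_units`.
#' @seealso [classify_record()] for the one-call convenience wrapper.
#' @export
classify_session <- function(record, breaths, efforts = NULL, match = NULL,
                             cfg = classifier_config()) {
  stopifnot(inherits(record, "waveform_record"))
  cfg <- as_classifier_config(cfg)
  has_pes <- !is.null(record$pes) && !is.null(efforts) && !is.null(match)
  if (has_pes && nrow(match$links)) {
    if (max(match$links$breath_index) > nrow(breaths) ||
        max(match$links$effort_index) > nrow(efforts))
      stop("classify_session: match result inconsistent with inputs")
  }
  nb <- nrow(breaths)
  events <- list()
  pes_base <- if (!is.null(record$pes))
    pes_baseline(record$pes, record$sample_rate_hz, cfg)

  # double breaths first (their suppression affects other calls)
  db_second <- logical(nb)
  if (nb >= 2L) {
    for (b in 2L:nb) {
      ev <- detect_double_breath(breaths[b - 1L, ], breaths[b, ], cfg)
      if (nrow(ev)) {
        ev$breath_index <- b
        db_second[b] <- TRUE
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  db_first <- c(db_second[-1L], FALSE)

  if (has_pes) {
    # trigger phase: TD on matched breaths, IE on effort cycles
    if (nrow(match$links)) {
      for (r in seq_len(nrow(match$links))) {
        rt <- match$links$response_time_ms[r]
        b <- match$links$breath_index[r]
        lab <- classify_trigger_timing(max(rt, 0), cfg)
        if (lab == "TD") {
          events[[length(events) + 1L]] <-
            make_event(breaths$onset_time_s[b], "TD", breath_index = b,
                       metric_value = rt, metric_units = "ms")
        }
        # cycling phase (EC suppressed on first cycles of DB pairs)
        e <- match$links$effort_index[r]
        cy <- detect_cycling(breaths[b, ], efforts[e, ], cfg)
        if (nrow(cy) && !(cy$type == "EC" && db_first[b])) {
          cy$breath_index <- b
          events[[length(events) + 1L]] <- cy
        }
      }
    }
    ie <- detect_ie_pes(match, efforts, cfg)
    if (nrow(ie)) events[[length(events) + 1L]] <- ie
    # auto-triggering on unmatched breaths (not second cycles of a DB)
    for (b in setdiff(match$unmatched_breaths, which(db_second))) {
      at <- detect_auto_trigger(record, breaths[b, ], cfg, pes_base)
      if (nrow(at)) {
        at$breath_index <- b
        events[[length(events) + 1L]] <- at
      }
    }
  } else {
    # flow-only paths
    for (b in seq_len(nb)) {
      ie <- detect_ie_flow(record, breaths[b, ], cfg)
      if (nrow(ie)) {
        ie$breath_index <- b
        events[[length(events) + 1L]] <- ie
      }
      if (!db_first[b]) {
        ec <- detect_ec_flow(record, breaths[b, ], cfg)
        if (nrow(ec)) {
          ec$breath_index <- b
          events[[length(events) + 1L]] <- ec
        }
      }
      if (!db_second[b]) {
        at <- detect_auto_trigger(record, breaths[b, ], cfg)
        if (nrow(at)) {
          at$breath_index <- b
          events[[length(events) + 1L]] <- at
        }
      }
    }
  }

  out <- if (length(events)) do.call(rbind, events) else empty_events()
  if (nrow(out)) {
    # drop events in masked windows (their breaths are dropped from the
    # denominator by the masked flag on breath segments)
    rate <- record$sample_rate_hz
    idx <- pmin(pmax(as.integer(round(out$time_s * rate)) + 1L, 1L),
                length(record$artifact_mask))
    keep <- !record$artifact_mask[idx]
    bi <- out$breath_index
    keep <- keep & (is.na(bi) | !breaths$masked[pmin(pmax(bi, 1L), max(nb, 1L))])
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$time_s), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Segment, match and classify a record in one call
#'
#' Convenience wrapper: masks artifacts, detects breaths and (when Pes is
#' present) efforts, matches them and runs [classify_session()].
#'
#' @param record A [waveform_record()].
#' @param cfg A [classifier_config()].
#' @param mask If `TRUE` (default), run [mask_artifacts()] first.
#' @return A list with `record` (masked), `breaths`, `efforts`, `match` and
#'   `events`.
#' @export
classify_record <- function(record, cfg = classifier_config(), mask = TRUE) {
  cfg <- as_classifier_config(cfg)
  if (mask) record <- mask_artifacts(record, cfg)
  breaths <- detect_breaths(record, cfg)
  efforts <- NULL; mres <- NULL
  if (!is.null(record$pes)) {
    efforts <- detect_efforts(record, cfg)
    mres <- match_efforts(breaths, efforts, cfg)
  }
  events <- classify_session(record, breaths, efforts, mres, cfg)
  list(record = record, breaths = breaths, efforts = efforts,
       match = mres, events = events)
}
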