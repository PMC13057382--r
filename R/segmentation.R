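# Breath and effort segmentation: the waveform-analysis primitives.
#
# Machine breaths are delimited by the pressurization of the airway-pressure
# channel; the onset is refined to the interpolated upward flow crossing and
# the inspiration-to-expiration transition ("cycle") to the interpolated fall
# of Paw below PEEP + paw_cycle_frac * PS. When the pressure channel is flat
# (no pressurization information), flow-only fallbacks are used: cycling at
# the onset of expiratory exponential decay, then at the downward
# zero-crossing of flow.

#' Fit an exponential decay to a flow window
#'
#' Least-squares fit of `log |flow|` against time. Exponential decay of flow
#' over time indicates passive conditions (relaxed respiratory muscles);
#' deviations from it during expiration indicate early cycling or ineffective
#' efforts. Samples with `|flow|` below `cfg$decay_floor_lpm` are excluded.
#'
#' @param flow_window Flow samples (L/min), all of one sign (or zero).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param cfg A [classifier_config()].
#' @return A list with `tau_s` (time constant, `NA` on failure),
#'   `r_squared`, `window_start_s`, `window_end_s`, `is_passive` and
#'   `n_used`. `is_passive` requires `r_squared >= cfg$passive_r2_min` and
#'   `tau_s` within `[cfg$tau_min_s, cfg$tau_max_s]`.
#' @export
fit_passive_decay <- function(flow_window, sample_rate_hz,
                              cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  n <- length(flow_window)
  out <- list(tau_s = NA_real_, r_squared = 0,
              window_start_s = 0, window_end_s = (n - 1) / sample_rate_hz,
              is_passive = FALSE, n_used = 0L)
  if (n < 8L) return(out)
  mag <- abs(flow_window)
  use <- which(mag > cfg$decay_floor_lpm)
  if (length(use) < 8L) return(out)
  tt <- (use - 1L) / sample_rate_hz
  fit <- fast_lsq(tt, log(mag[use]))
  out$n_used <- length(use)
  out$r_squared <- max(0, min(1, fit$r2))
  if (is.finite(fit$slope) && fit$slope < 0) {
    out$tau_s <- -1 / fit$slope
    out$is_passive <- out$r_squared >= cfg$passive_r2_min &&
      out$tau_s >= cfg$tau_min_s && out$tau_s <= cfg$tau_max_s
  }
  out
}

#' Detect machine breaths
#'
#' Segments a record into non-overlapping machine-breath cycles. The onset of
#' each breath is the interpolated upward crossing of the flow-deflection
#' threshold just before pressurization; the cycle time is the interpolated
#' fall of airway pressure below PEEP + `paw_cycle_frac` * PS (flow-based
#' fallbacks when the pressure channel carries no pressurization); the end is
#' the next onset or the record end. Phase volumes are trapezoidal integrals
#' of flow.
#'
#' @param record A [waveform_record()].
#' @param cfg A [classifier_config()].
#' @return A data frame of class `breath_segments`, one row per breath:
#'   `onset_time_s`, `cycle_time_s`, `end_time_s`, `ti_s`, `te_s`,
#'   `peak_insp_flow_lpm`, `v_insp_ml`, `v_exp_ml`, `passive_insp`,
#'   `passive_exp`, `masked`.
#' @export
detect_breaths <- function(record, cfg = classifier_config()) {
  stopifnot(inherits(record, "waveform_record"))
  cfg <- as_classifier_config(cfg)
  rate <- record$sample_rate_hz
  n <- length(record$paw)
  paw_s <- moving_average(record$paw, 3L)
  flow_s <- moving_average(record$flow, 3L)
  lev <- estimate_paw_levels(record$paw)
  empty <- data.frame(onset_time_s = numeric(0), cycle_time_s = numeric(0),
                      end_time_s = numeric(0), ti_s = numeric(0),
                      te_s = numeric(0), peak_insp_flow_lpm = numeric(0),
                      v_insp_ml = numeric(0), v_exp_ml = numeric(0),
                      passive_insp = logical(0), passive_exp = logical(0),
                      masked = logical(0))
  class(empty) <- c("breath_segments", "data.frame")

  paw_informative <- lev$ps >= 1
  if (paw_informative) {
    runs <- true_runs(paw_s > lev$peep + 0.5 * lev$ps)
  } else {
    # flow-only: pressurization invisible; treat sustained positive flow as
    # inspiration
    runs <- true_runs(flow_s > cfg$breath_flow_onset_lpm)
  }
  if (!nrow(runs)) return(empty)
  min_len <- as.integer(round(0.12 * rate))
  runs <- runs[runs[, 2L] - runs[, 1L] + 1L >= min_len, , drop = FALSE]
  if (!nrow(runs)) return(empty)

  look <- as.integer(round(0.3 * rate))
  onsets <- numeric(nrow(runs))
  cycles <- numeric(nrow(runs))
  keep <- logical(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    si <- runs[r, 1L]; ei <- runs[r, 2L]
    from <- max(1L, si - look)
    # onset: the start of pressurization is the sharpest marker when the
    # pressure channel is informative (its early rise is steep regardless of
    # patient mechanics); otherwise the upward flow-deflection crossing
    onset <- NA_real_
    if (paw_informative) {
      cp <- crossing_times(paw_s, lev$peep + 0.12 * lev$ps, rate, dir = 1L,
                           from = from, to = min(si + 2L, n))
      if (length(cp)) onset <- cp[length(cp)]
    }
    if (!is.finite(onset)) {
      cr <- crossing_times(flow_s, cfg$breath_flow_onset_lpm, rate, dir = 1L,
                           from = from, to = min(si + 3L, n))
      onset <- if (length(cr)) cr[length(cr)] else (si - 1L) / rate
    }
    # cycle: Paw falling out of the support plateau
    cyc <- NA_real_
    if (paw_informative) {
      thr <- lev$peep + cfg$paw_cycle_frac * lev$ps
      cc <- crossing_times(paw_s, thr, rate, dir = -1L,
                           from = max(si, 2L), to = min(ei + as.integer(0.4 * rate), n))
      if (length(cc)) cyc <- cc[length(cc)]
    }
    if (!is.finite(cyc)) {
      # fallback: expiratory decay onset approximated by the peak expiratory
      # flow, preceded by the downward zero-crossing of flow
      stop_i <- if (r < nrow(runs)) runs[r + 1L, 1L] else n
      oi <- max(1L, as.integer(round(onset * rate)) + 1L)
      pk <- oi - 1L + which.max(flow_s[oi:min(ei + 2L, n)])
      zc <- crossing_times(flow_s, 0, rate, dir = -1L, from = pk, to = stop_i)
      cyc <- if (length(zc)) zc[1L] else NA_real_
    }
    if (is.finite(cyc) && cyc > onset + 0.05) {
      onsets[r] <- onset; cycles[r] <- cyc; keep[r] <- TRUE
    }
  }
  onsets <- onsets[keep]; cycles <- cycles[keep]
  if (!length(onsets)) return(empty)
  ends <- c(onsets[-1L], (n - 1L) / rate)
  # guard against overlap from a missed cycle
  ok <- cycles < ends
  onsets <- onsets[ok]; cycles <- cycles[ok]; ends <- ends[ok]
  if (!length(onsets)) return(empty)

  nb <- length(onsets)
  pif <- v_in <- v_ex <- numeric(nb)
  p_in <- p_ex <- logical(nb)
  msk <- logical(nb)
  oi <- pmax(1L, as.integer(floor(onsets * rate)) + 1L)
  ci <- pmin(n, as.integer(ceiling(cycles * rate)) + 1L)
  ei2 <- pmin(n, as.integer(floor(ends * rate)) + 1L)
  for (b in seq_len(nb)) {
    ins <- oi[b]:ci[b]
    pif[b] <- max(record$flow[ins])
    v_in[b] <- integrate_volume(record$flow, rate, oi[b], ci[b])
    v_ex[b] <- max(0, -integrate_volume(record$flow, rate, ci[b], ei2[b]))
    # passivity of each phase from the flow shape
    pk_i <- ins[which.max(flow_s[ins])]
    if (ci[b] - pk_i >= 8L) {
      p_in[b] <- fit_passive_decay(flow_s[pk_i:ci[b]], rate, cfg)$is_passive
    }
    exp_win <- ci[b]:ei2[b]
    if (length(exp_win) >= 8L) {
      pef_i <- exp_win[which.min(flow_s[exp_win])]
      if (ei2[b] - pef_i >= 8L) {
        p_ex[b] <- fit_passive_decay(flow_s[pef_i:ei2[b]], rate, cfg)$is_passive
      }
    }
    span <- oi[b]:ei2[b]
    msk[b] <- mean(record$artifact_mask[span]) > 0.1
  }
  out <- data.frame(onset_time_s = onsets, cycle_time_s = cycles,
                    end_time_s = ends, ti_s = cycles - onsets,
                    te_s = ends - cycles, peak_insp_flow_lpm = pif,
                    v_insp_ml = v_in, v_exp_ml = v_ex,
                    passive_insp = p_in, passive_exp = p_ex, masked = msk)
  class(out) <- c("breath_segments", "data.frame")
  out
}

# Rolling-median esophageal-pressure baseline used by effort detection and
# the auto-trigger veto.
pes_baseline <- function(pes, rate, cfg) {
  k <- as.integer(cfg$pes_baseline_win_s * rate)
  if (k %% 2L == 0L) k <- k + 1L
  if (length(pes) > k) as.numeric(stats::runmed(pes, k, endrule = "median"))
  else rep(stats::median(pes), length(pes))
}

#' Detect patient inspiratory efforts on the esophageal pressure channel
#'
#' An effort is a contiguous negative Pes deflection from the rolling-median
#' baseline with amplitude at least `cfg$pes_effort_min_cmh2o`. The onset is
#' the interpolated crossing of `baseline - pes_onset_frac * amplitude`; the
#' termination is the interpolated point on the post-nadir rise where Pes
#' crosses the midpoint between nadir and baseline (the end of the patient's
#' neural inspiration).
#'
#' @param record A [waveform_record()] with a `pes` channel.
#' @param cfg A [classifier_config()].
#' @return A data frame of class `effort_events`, one row per effort:
#'   `onset_time_s`, `nadir_time_s`, `termination_time_s`,
#'   `amplitude_cmh2o`.
#' @export
detect_efforts <- function(record, cfg = classifier_config()) {
  stopifnot(inherits(record, "waveform_record"))
  if (is.null(record$pes))
    stop("detect_efforts: record has no pes channel; use flow-only paths")
  cfg <- as_classifier_config(cfg)
  rate <- record$sample_rate_hz
  pes_s <- moving_average(record$pes, 7L)
  base <- pes_baseline(record$pes, rate, cfg)
  dev <- base - pes_s  # positive during inspiratory (negative Pes) deflection
  n <- length(dev)
  empty <- data.frame(onset_time_s = numeric(0), nadir_time_s = numeric(0),
                      termination_time_s = numeric(0),
                      amplitude_cmh2o = numeric(0))
  class(empty) <- c("effort_events", "data.frame")
  region_thr <- 0.5 * cfg$pes_effort_min_cmh2o
  runs <- true_runs(dev > region_thr)
  if (!nrow(runs)) return(empty)
  # merge regions split by brief noise dips
  gap_max <- as.integer(round(0.1 * rate))
  if (nrow(runs) > 1L) {
    merged <- list(runs[1L, ])
    for (r in 2L:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[r, 1L] - last[2L] <= gap_max) {
        merged[[length(merged)]][2L] <- runs[r, 2L]
      } else merged[[length(merged) + 1L]] <- runs[r, ]
    }
    runs <- do.call(rbind, merged)
  }
  res <- vector("list", nrow(runs))
  back <- as.integer(round(1.5 * rate))
  q_far <- as.integer(round(0.35 * rate))
  q_near <- as.integer(round(0.06 * rate))
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, 1L]; b <- runs[r, 2L]
    nad <- a + which.min(pes_s[a:b]) - 1L
    # amplitude and thresholds against a local pre-effort quiet-window
    # baseline: the rolling median is robust for region finding but biased
    # low where efforts occupy much of its window, which would delay onsets
    qa <- max(1L, a - q_far); qb <- max(1L, a - q_near)
    local_base <- if (qb - qa >= 5L) {
      # linear fit extrapolated to the region start: with slow respiratory
      # mechanics the esophageal pressure still drifts late in expiration
      # (incomplete lung emptying), so a window median would sit high
      qf <- fast_lsq((qa:qb) / rate, pes_s[qa:qb])
      slope <- max(min(qf$slope, 1), -1)
      mean(pes_s[qa:qb]) + slope * (a - (qa + qb) / 2) / rate
    } else base[nad]
    amp <- local_base - pes_s[nad]
    if (amp < cfg$pes_effort_min_cmh2o) next
    on_cr <- crossing_times(pes_s, local_base - cfg$pes_onset_frac * amp,
                            rate, dir = -1L, from = max(1L, nad - back),
                            to = nad)
    term_cr <- crossing_times(pes_s, (pes_s[nad] + local_base) / 2, rate,
                              dir = 1L, from = nad, to = min(n, nad + back))
    onset <- if (length(on_cr)) on_cr[length(on_cr)] else (a - 1L) / rate
    term <- if (length(term_cr)) term_cr[1L] else (b - 1L) / rate
    nad_t <- (nad - 1L) / rate
    if (onset < nad_t && nad_t < term) {
      res[[r]] <- c(onset, nad_t, term, amp)
    }
  }
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) return(empty)
  out <- data.frame(onset_time_s = res[, 1L], nadir_time_s = res[, 2L],
                    termination_time_s = res[, 3L], amplitude_cmh2o = res[, 4L])
  class(out) <- c("effort_events", "data.frame")
  out
}

#' Match patient efforts to machine breaths
#'
#' Greedy chronological one-to-one matching: each effort, in time order,
#' links to the earliest unmatched breath whose onset lies within
#' `[effort onset - pre_trigger_tol_ms, effort onset + match_window_ms]`.
#' The ventilator response time of a link is
#' `1000 * (breath onset - effort onset)` ms.
#'
#' @param breaths A `breath_segments` data frame from [detect_breaths()].
#' @param efforts An `effort_events` data frame from [detect_efforts()].
#' @param cfg A [classifier_config()].
#' @return A list of class `match_result`: `links` (data frame with
#'   `effort_index`, `breath_index`, `response_time_ms`),
#'   `unmatched_breaths` and `unmatched_efforts` (integer indices).
#' @export
match_efforts <- function(breaths, efforts, cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  nb <- nrow(breaths); ne <- nrow(efforts)
  taken <- logical(nb)
  links <- vector("list", ne)
  lo <- -cfg$pre_trigger_tol_ms / 1000
  hi <- cfg$match_window_ms / 1000
  if (ne && nb) {
    for (e in seq_len(ne)) {
      d <- breaths$onset_time_s - efforts$onset_time_s[e]
      ok <- which(!taken & d >= lo & d <= hi)
      if (length(ok)) {
        b <- ok[1L]
        taken[b] <- TRUE
        links[[e]] <- c(e, b, 1000 * d[b])
      }
    }
  }
  links <- do.call(rbind, links[!vapply(links, is.null, logical(1))])
  links <- if (is.null(links)) {
    data.frame(effort_index = integer(0), breath_index = integer(0),
               response_time_ms = numeric(0))
  } else {
    data.frame(effort_index = as.integer(links[, 1L]),
               breath_index = as.integer(links[, 2L]),
               response_time_ms = links[, 3L])
  }
  structure(list(
    links = links,
    unmatched_breaths = setdiff(seq_len(nb), links$breath_index),
    unmatched_efforts = setdiff(seq_len(ne), links$effort_index)
  ), class = "match_result")
}
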