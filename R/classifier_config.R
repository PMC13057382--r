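#' Classifier configuration
#'
#' Bundles every threshold used by breath segmentation, effort detection and
#' asynchrony classification. The trigger-timing bins, the ineffective-effort
#' airway-pressure drop and the early-cycling offset follow the published
#' waveform-analysis convention for pressure-support ventilation; the
#' remaining thresholds are tunable detection parameters with pediatric
#' defaults.
#'
#' Timing bins are realized on continuous time as half-open intervals:
#' response times in (0, `normal_trigger_max_ms`] are normal,
#' (`normal_trigger_max_ms`, `td_max_ms`] are trigger delay (TD) and
#' > `td_max_ms` are ineffective efforts (IE).
#'
#' @param normal_trigger_max_ms Upper bound (ms) of the normal trigger band
#'   (default 117).
#' @param td_max_ms Upper bound (ms) of the trigger-delay band (default 234);
#'   response times beyond this are classified IE.
#' @param ie_paw_drop_cmh2o Minimum abrupt airway-pressure drop (cmH2O)
#'   accompanying an expiratory flow notch for flow-only IE detection
#'   (default 0.5).
#' @param ec_lc_offset_ms Cycling-offset threshold (ms): ventilator cycling
#'   preceding patient inspiratory termination by at least this much is early
#'   cycling (EC); the symmetric negative threshold defines late cycling (LC).
#'   Default 100.
#' @param db_te_ti_ratio Double-breath rule: an interposed expiratory time at
#'   or below this fraction of the first cycle's inspiratory time labels the
#'   second cycle DB (default 0.5).
#' @param pes_ie_delay_ms Delay (ms) after effort onset within which a
#'   ventilator breath must start for the effort to count as triggered when
#'   esophageal pressure is available; efforts not followed within this delay
#'   are IE (default 234, aligning the Pes rule with the trigger-timing bins).
#' @param passive_r2_min Minimum r-squared of the log-linear expiratory decay
#'   fit for a window to be called passive (default 0.95).
#' @param tau_min_s,tau_max_s Admissible expiratory time-constant range (s)
#'   for a passive decay (defaults 0.05 and 1.5, pediatric range).
#' @param decay_floor_lpm Flow magnitude (L/min) below which samples are
#'   excluded from decay fitting (default 2).
#' @param ie_flow_dev_lpm Minimum deviation of expiratory flow toward zero
#'   above the fitted passive envelope for flow-only IE detection (default 3).
#' @param pes_effort_min_cmh2o Minimum esophageal-pressure deflection
#'   amplitude (cmH2O) to count as an inspiratory effort (default 1).
#' @param pes_onset_frac Fraction of the deflection amplitude at which the
#'   interpolated effort onset is placed (default 0.12: about 1 cmH2O on a
#'   typical pediatric effort, the smallest deflection that stands clear of
#'   esophageal signal noise, and a steep enough point of the effort for
#'   low-jitter timing).
#' @param pes_baseline_win_s Width (s) of the centered rolling-median Pes
#'   baseline (default 4).
#' @param match_window_ms Effort-to-breath matching window (ms) after effort
#'   onset (default 600).
#' @param pre_trigger_tol_ms Tolerance (ms) for a breath onset slightly
#'   preceding its effort onset (default 80; the flow-based breath onset and
#'   the Pes-based effort onset are independent estimators with tens of
#'   milliseconds of jitter on noisy channels).
#' @param breath_flow_onset_lpm Flow threshold (L/min) whose interpolated
#'   upward crossing marks the machine-breath onset (default 2).
#' @param paw_cycle_frac Fraction of the support level whose downward
#'   airway-pressure crossing marks the inspiration-to-expiration transition
#'   (default 0.8).
#' @param at_paw_dip_cmh2o,at_pes_dip_cmh2o Minimum pre-onset negative
#'   deflections (cmH2O) in airway / esophageal pressure that indicate a
#'   patient effort and therefore veto an auto-trigger call (defaults 0.25
#'   and 0.5).
#' @param pre_onset_win_ms Window (ms) before an unmatched breath onset that
#'   is searched for effort-related deflections (default 300).
#' @param cough_flow_spike_lpm Positive expiratory-flow spike (L/min) above
#'   which samples are masked as cough artifact (default 10).
#' @param active_exp_pes_cmh2o Positive esophageal-pressure transient (cmH2O)
#'   above baseline masked as active expiration (default 3).
#' @param artifact_pad_s Padding (s) added around masked artifact windows
#'   (default 0.3).
#'
#' @return An object of class `classifier_config` (a validated named list).
#' @examples
#' cfg <- classifier_config()
#' cfg$normal_trigger_max_ms
#' @export
classifier_config <- function(normal_trigger_max_ms = 117,
                              td_max_ms = 234,
                              ie_paw_drop_cmh2o = 0.5,
                              ec_lc_offset_ms = 100,
                              db_te_ti_ratio = 0.5,
                              pes_ie_delay_ms = 234,
                              passive_r2_min = 0.95,
                              tau_min_s = 0.05,
                              tau_max_s = 1.5,
                              decay_floor_lpm = 2,
                              ie_flow_dev_lpm = 3,
                              pes_effort_min_cmh2o = 1,
                              pes_onset_frac = 0.12,
                              pes_baseline_win_s = 4,
                              match_window_ms = 600,
                              pre_trigger_tol_ms = 80,
                              breath_flow_onset_lpm = 2,
                              paw_cycle_frac = 0.8,
                              at_paw_dip_cmh2o = 0.25,
                              at_pes_dip_cmh2o = 0.5,
                              pre_onset_win_ms = 300,
                              cough_flow_spike_lpm = 10,
                              active_exp_pes_cmh2o = 3,
                              artifact_pad_s = 0.3) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$normal_trigger_max_ms > 0,
    cfg$td_max_ms > cfg$normal_trigger_max_ms,
    cfg$ie_paw_drop_cmh2o > 0,
    cfg$ec_lc_offset_ms > 0,
    cfg$db_te_ti_ratio > 0, cfg$db_te_ti_ratio <= 1,
    cfg$pes_ie_delay_ms > 0,
    cfg$passive_r2_min > 0, cfg$passive_r2_min <= 1,
    cfg$tau_min_s > 0, cfg$tau_max_s > cfg$tau_min_s,
    cfg$decay_floor_lpm >= 0,
    cfg$pes_effort_min_cmh2o > 0,
    cfg$pes_onset_frac > 0, cfg$pes_onset_frac < 1,
    cfg$pes_baseline_win_s > 0,
    cfg$match_window_ms > 0,
    cfg$pre_trigger_tol_ms >= 0,
    cfg$paw_cycle_frac > 0, cfg$paw_cycle_frac < 1
  )
  structure(cfg, class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config>\n")
  cat(sprintf("  trigger bins: normal <= %g ms < TD <= %g ms < IE\n",
              x$normal_trigger_max_ms, x$td_max_ms))
  cat(sprintf("  IE flow rule: Paw drop >= %g cmH2O, flow deviation >= %g L/min\n",
              x$ie_paw_drop_cmh2o, x$ie_flow_dev_lpm))
  cat(sprintf("  cycling offset threshold: +/- %g ms; DB Te/Ti <= %g\n",
              x$ec_lc_offset_ms, x$db_te_ti_ratio))
  cat(sprintf("  passivity: r2 >= %g, tau in [%g, %g] s\n",
              x$passive_r2_min, x$tau_min_s, x$tau_max_s))
  invisible(x)
}

as_classifier_config <- function(x) {
  if (inherits(x, "classifier_config")) return(x)
  if (is.null(x)) return(classifier_config())
  do.call(classifier_config, x)
}
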