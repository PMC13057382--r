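# Fixtures and independent oracles used across the test files.

# A single machine breath as an idealized trace: square inspiratory flow of
# `insp_lpm` for `ti_s`, then exponential expiratory decay with time
# constant `tau_s`, embedded in `pad_s` of silence on both sides. The Paw
# channel pressurizes to peep + ps over the inspiration.
square_breath_record <- function(insp_lpm = 12, ti_s = 1, tau_s = 0.3,
                                 peak_exp_lpm = -20, pad_s = 2,
                                 duration_exp_s = 2, rate = 50,
                                 peep = 5, ps = 8) {
  n_pad <- pad_s * rate
  n_ti <- ti_s * rate
  n_exp <- duration_exp_s * rate
  t_exp <- (seq_len(n_exp) - 1) / rate
  flow <- c(rep(0, n_pad), rep(insp_lpm, n_ti),
            peak_exp_lpm * exp(-t_exp / tau_s), rep(0, n_pad))
  paw <- c(rep(peep, n_pad), rep(peep + ps, n_ti),
           rep(peep, n_exp + n_pad))
  waveform_record(paw = paw, flow = flow, sample_rate_hz = rate)
}

# Raised-cosine esophageal effort identical in shape to the simulator's
# Pmus pulse: rise over ti, release over rel; returns the record plus the
# analytic midpoint-crossing (termination) time.
pes_effort_record <- function(amp = 8, ti = 0.7, rel = 0.35, t0 = 3,
                              duration = 8, rate = 50, baseline = -3) {
  tt <- (seq_len(duration * rate) - 1) / rate
  pmus <- numeric(length(tt))
  rise <- tt >= t0 & tt <= t0 + ti
  pmus[rise] <- amp * sin((tt[rise] - t0) * pi / (2 * ti))^2
  fall <- tt > t0 + ti & tt <= t0 + ti + rel
  pmus[fall] <- amp * cos((tt[fall] - t0 - ti) * pi / (2 * rel))^2
  rec <- waveform_record(paw = rep(5, length(tt)), flow = rep(0, length(tt)),
                         sample_rate_hz = rate, pes = baseline - pmus)
  list(record = rec, onset = t0, nadir = t0 + ti,
       termination = t0 + ti + rel / 2, amplitude = amp)
}

# Brute-force effort/breath matcher: enumerates all assignments of efforts
# to in-window breaths and returns the maximum number of matched pairs.
brute_force_max_matching <- function(breath_onsets, effort_onsets, cfg) {
  lo <- -cfg$pre_trigger_tol_ms / 1000
  hi <- cfg$match_window_ms / 1000
  ne <- length(effort_onsets)
  best <- 0L
  recurse <- function(e, used) {
    if (e > ne) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    d <- breath_onsets - effort_onsets[e]
    ok <- which(!used & d >= lo & d <= hi)
    for (b in ok) {
      used[b] <- TRUE
      recurse(e + 1L, used)
      used[b] <- FALSE
    }
    recurse(e + 1L, used)  # leave effort unmatched
  }
  recurse(1L, logical(length(breath_onsets)))
  best
}

# Independent reference classifier: applies each labeling rule exhaustively,
# one at a time, then resolves precedence in the documented order. Shares
# only the low-level feature extractors (deflection measurement) with the
# production path; the rule application and precedence logic are separate.
reference_classify <- function(record, breaths, efforts, match, cfg) {
  nb <- nrow(breaths)
  rows <- list()
  add <- function(time_s, type, bi = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time_s = time_s, breath_index = as.integer(bi), type = type,
      stringsAsFactors = FALSE)
  }
  # rule: double breath
  db_second <- rep(FALSE, nb)
  if (nb >= 2L) for (b in 2L:nb) {
    te <- breaths$end_time_s[b - 1L] - breaths$cycle_time_s[b - 1L]
    if (te <= cfg$db_te_ti_ratio * breaths$ti_s[b - 1L]) {
      db_second[b] <- TRUE
      add(breaths$onset_time_s[b], "DB", b)
    }
  }
  db_first <- c(db_second[-1L], FALSE)
  # rule: trigger timing on matched pairs
  links <- match$links
  for (r in seq_len(nrow(links))) {
    rt <- max(links$response_time_ms[r], 0)
    b <- links$breath_index[r]; e <- links$effort_index[r]
    if (rt > cfg$td_max_ms) {
      add(efforts$onset_time_s[e], "IE")
    } else if (rt > cfg$normal_trigger_max_ms) {
      add(breaths$onset_time_s[b], "TD", b)
    }
    # rule: cycling offset
    off <- 1000 * (efforts$termination_time_s[e] - breaths$cycle_time_s[b])
    if (off >= cfg$ec_lc_offset_ms && !db_first[b]) {
      add(breaths$cycle_time_s[b], "EC", b)
    } else if (off <= -cfg$ec_lc_offset_ms) {
      add(breaths$cycle_time_s[b], "LC", b)
    }
  }
  # rule: ineffective efforts (unmatched)
  for (e in match$unmatched_efforts) add(efforts$onset_time_s[e], "IE")
  # rule: auto-triggering on unmatched, non-DB-second breaths
  pes_base <- if (!is.null(record$pes))
    ventsync:::pes_baseline(record$pes, record$sample_rate_hz, cfg)
  for (b in match$unmatched_breaths) {
    if (db_second[b]) next
    f <- ventsync:::pre_onset_deflections(record, breaths$onset_time_s[b],
                                          cfg, pes_base)
    effort_seen <- (is.finite(f$paw_dip) && f$paw_dip >= cfg$at_paw_dip_cmh2o) ||
      (is.finite(f$pes_dip) && f$pes_dip >= cfg$at_pes_dip_cmh2o)
    if (!effort_seen) add(breaths$onset_time_s[b], "AT", b)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(0), breath_index = integer(0),
               type = character(0), stringsAsFactors = FALSE)
  # drop masked
  if (nrow(out)) {
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

# A short simulated session (about a dozen machine breaths) with elevated
# injection rates, for micro-scale oracle tests.
micro_session <- function(seed, duration_s = 60) {
  pm <- patient_model(neural_rate_bpm = 10, neural_ti_s = 0.9)
  vs <- vent_settings()
  pr <- asynchrony_profile(rates_per_min = c(IE = 0.8, AT = 0.5, DB = 0.5,
                                             TD = 1, EC = 1, LC = 0.5))
  simulate_session(pm, vs, pr, duration_s = duration_s, seed = seed)
}
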