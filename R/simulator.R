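# Synthetic pressure-support ventilation sessions with injectable
# patient-ventilator asynchronies and ground-truth event logs.
#
# The simulator is schedule-driven: a breath-by-breath planner realizes the
# ventilator state machine (flow-triggering with valve latency, cycling at
# the patient's neural inspiratory termination with jitter, or forced
# early/late cycling and re-triggering for injected events) as explicit
# trigger/cycle times, then the waveforms are synthesized by integrating the
# single-compartment equation of motion
#     flow = (Paw + Pmus - PEEP - V/C) / R,
#     Pes  = Pes_baseline + V * Ecw - Pmus
# with an exact exponential-integrator step at the sampling rate. Every
# injected event is logged with its realized metric, so detection can be
# scored against ground truth.

#' Patient respiratory model
#'
#' Single-compartment mechanics plus a neural breathing pattern. The
#' inspiratory muscle-pressure (Pmus) waveform is a raised cosine: rising
#' over the neural inspiratory time, releasing over half that time; the
#' neural inspiratory termination (the quantity cycling errors are measured
#' against) is the midpoint of the release.
#'
#' Default resistance/compliance by lung physiology profile
#' (cmH2O.s/L, mL/cmH2O): normal 25/15, obstructive 60/14, restrictive
#' 30/8, mixed 45/9 — pediatric invasive-ventilation ranges.
#'
#' @param physiology_profile One of `"normal"`, `"obstructive"`,
#'   `"restrictive"`, `"mixed"`.
#' @param resistance_cmh2o_s_per_l Airway resistance; default from profile.
#' @param compliance_ml_per_cmh2o Respiratory-system compliance; default
#'   from profile.
#' @param chest_wall_elastance_cmh2o_per_ml Chest-wall elastance coupling
#'   volume into Pes (default 0.005).
#' @param pmus_max_cmh2o Inspiratory muscle pressure amplitude (default 8).
#' @param neural_rate_bpm Neural respiratory rate (default 28/min).
#' @param neural_ti_s Neural inspiratory time (default 0.7 s); must be less
#'   than the breath period.
#' @param rate_variability_cv Coefficient of variation of the breath period
#'   (default 0.08).
#' @param pmus_variability_cv Log-normal per-breath jitter of the Pmus
#'   amplitude (default 0.15).
#' @param pes_baseline_cmh2o Esophageal pressure baseline (default -3).
#' @param noise_sd Named list of per-channel Gaussian noise SDs
#'   (`paw`, `flow`, `pes`).
#' @return An object of class `patient_model`.
#' @export
patient_model <- function(physiology_profile = c("mixed", "restrictive",
                                                 "obstructive", "normal"),
                          resistance_cmh2o_s_per_l = NULL,
                          compliance_ml_per_cmh2o = NULL,
                          chest_wall_elastance_cmh2o_per_ml = 0.005,
                          pmus_max_cmh2o = 8,
                          neural_rate_bpm = 28,
                          neural_ti_s = 0.7,
                          rate_variability_cv = 0.08,
                          pmus_variability_cv = 0.15,
                          pes_baseline_cmh2o = -3,
                          noise_sd = list(paw = 0.1, flow = 0.5, pes = 0.15)) {
  physiology_profile <- match.arg(physiology_profile)
  rc <- switch(physiology_profile,
               normal = c(25, 15), obstructive = c(60, 14),
               restrictive = c(30, 8), mixed = c(45, 9))
  r <- resistance_cmh2o_s_per_l %||% rc[1L]
  c_ <- compliance_ml_per_cmh2o %||% rc[2L]
  stopifnot(r > 0, c_ > 0, chest_wall_elastance_cmh2o_per_ml >= 0,
            pmus_max_cmh2o >= 0, neural_rate_bpm > 0, neural_ti_s > 0,
            rate_variability_cv >= 0,
            neural_ti_s < 60 / neural_rate_bpm)
  structure(list(
    physiology_profile = physiology_profile,
    resistance_cmh2o_s_per_l = r,
    compliance_ml_per_cmh2o = c_,
    chest_wall_elastance_cmh2o_per_ml = chest_wall_elastance_cmh2o_per_ml,
    pmus_max_cmh2o = pmus_max_cmh2o,
    neural_rate_bpm = neural_rate_bpm,
    neural_ti_s = neural_ti_s,
    rate_variability_cv = rate_variability_cv,
    pmus_variability_cv = pmus_variability_cv,
    pes_baseline_cmh2o = pes_baseline_cmh2o,
    noise_sd = utils::modifyList(list(paw = 0.1, flow = 0.5, pes = 0.15),
                                 as.list(noise_sd))
  ), class = "patient_model")
}

#' Ventilator settings
#'
#' Pressure-support settings. `sync_mode = "conventional"` triggers on the
#' flow-trigger threshold with a valve latency and cycles near the neural
#' termination with clinician-set jitter; `"closed_loop_emulated"` is an
#' idealized waveform-following controller that triggers with a short
#' latency after the observable effort onset and cycles tightly at neural
#' termination. (The emulation is an oracle-synchronized stand-in, not a
#' reconstruction of any proprietary algorithm.)
#'
#' @param ps_cmh2o Pressure support above PEEP (default 8.5).
#' @param peep_cmh2o Positive end-expiratory pressure (default 5).
#' @param fio2_pct Inspired oxygen fraction, passthrough metadata
#'   (default 30).
#' @param p_ramp_ms Pressurization rise time constant (default 50).
#' @param flow_trigger_lpm Flow trigger (default 0.75 L/min).
#' @param ets_pct Expiratory trigger sensitivity, percent of peak
#'   inspiratory flow (default 30; informational in the schedule-driven
#'   realization).
#' @param sync_mode `"conventional"` or `"closed_loop_emulated"`.
#' @param max_ti_s Backup cycling time (default 1.3 s).
#' @return An object of class `vent_settings`.
#' @export
vent_settings <- function(ps_cmh2o = 8.5, peep_cmh2o = 5, fio2_pct = 30,
                          p_ramp_ms = 50, flow_trigger_lpm = 0.75,
                          ets_pct = 30,
                          sync_mode = c("conventional", "closed_loop_emulated"),
                          max_ti_s = 1.3) {
  sync_mode <- match.arg(sync_mode)
  stopifnot(ps_cmh2o >= 0, peep_cmh2o >= 0, p_ramp_ms > 0,
            flow_trigger_lpm > 0, ets_pct > 0, ets_pct < 100, max_ti_s > 0)
  structure(list(ps_cmh2o = ps_cmh2o, peep_cmh2o = peep_cmh2o,
                 fio2_pct = fio2_pct, p_ramp_ms = p_ramp_ms,
                 flow_trigger_lpm = flow_trigger_lpm, ets_pct = ets_pct,
                 sync_mode = sync_mode, max_ti_s = max_ti_s),
            class = "vent_settings")
}

#' Asynchrony injection profile
#'
#' Target per-minute rates for each event type and the injection mechanism
#' parameters. Events are scheduled by per-breath Bernoulli thinning with at
#' most one injected anomaly per neural breath, keeping ground truth
#' unambiguous. The default rates produce an overall Asynchrony Index near
#' the mid-teens typical of conventionally synchronized pediatric pressure
#' support.
#'
#' @param rates_per_min Named numeric vector of per-minute target rates for
#'   `IE`, `AT`, `DB`, `TD`, `EC`, `LC`.
#' @param ie_amp_frac Pmus amplitude fraction for weak (ineffective) efforts
#'   (default 0.4).
#' @param td_latency_range_ms Added trigger-latency range for TD injection
#'   (default 150-200 ms, inside the 118-234 ms band with margin for
#'   measurement jitter).
#' @param ec_offset_range_ms,lc_offset_range_ms Forced cycling-offset ranges
#'   (defaults 150-350 ms, beyond the 100 ms diagnostic threshold).
#' @param db_gap_frac Interposed expiratory gap of a double breath as a
#'   fraction of the first cycle's inspiratory time (default 0.35).
#' @param cough_rate_per_min Cough-artifact rate (default 0).
#' @return An object of class `asynchrony_profile`.
#' @export
asynchrony_profile <- function(rates_per_min = c(IE = 0.80, AT = 0.56,
                                                 DB = 0.36, TD = 1.57,
                                                 EC = 1.28, LC = 0.32),
                               ie_amp_frac = 0.4,
                               td_latency_range_ms = c(150, 200),
                               ec_offset_range_ms = c(150, 350),
                               lc_offset_range_ms = c(150, 350),
                               db_gap_frac = 0.35,
                               cough_rate_per_min = 0) {
  rates <- c(IE = 0, AT = 0, DB = 0, TD = 0, EC = 0, LC = 0)
  rates[names(rates_per_min)] <- rates_per_min
  stopifnot(all(is.finite(rates)), all(rates >= 0),
            cough_rate_per_min >= 0,
            td_latency_range_ms[1L] >= 118, td_latency_range_ms[2L] <= 234,
            ec_offset_range_ms[1L] >= 100, lc_offset_range_ms[1L] >= 100,
            db_gap_frac > 0, db_gap_frac <= 0.5,
            ie_amp_frac > 0, ie_amp_frac < 1)
  structure(list(rates_per_min = rates, ie_amp_frac = ie_amp_frac,
                 td_latency_range_ms = td_latency_range_ms,
                 ec_offset_range_ms = ec_offset_range_ms,
                 lc_offset_range_ms = lc_offset_range_ms,
                 db_gap_frac = db_gap_frac,
                 cough_rate_per_min = cough_rate_per_min),
            class = "asynchrony_profile")
}

#' Scale a profile's injection rates
#'
#' Multiplies each event type's per-minute rate by a (possibly per-type)
#' factor; used to derive a closed-loop arm profile from a conventional one.
#'
#' @param profile An [asynchrony_profile()].
#' @param factors Single number or named vector over event types.
#' @return The scaled profile.
#' @export
scale_profile <- function(profile, factors) {
  stopifnot(inherits(profile, "asynchrony_profile"))
  f <- rep(1, 6); names(f) <- names(profile$rates_per_min)
  if (is.null(names(factors))) f[] <- factors else f[names(factors)] <- factors
  profile$rates_per_min <- profile$rates_per_min * f
  profile
}

# Save/restore the global RNG state around a seeded computation.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Time after neural onset at which the raised-cosine effort becomes
# observable on Pes (crosses the onset-fraction threshold) or reaches the
# pressure needed to move the flow trigger.
effort_cross_time <- function(ti, frac) (2 * ti / pi) * asin(sqrt(min(frac, 0.95)))

# ---------------------------------------------------------------------------
# Breath-by-breath session planner.
# Returns machine intervals, Pmus pulses, cough times and the truth log.
plan_session <- function(patient, vent, profile, duration_s,
                         cfg_onset_frac = 0.12) {
  rates <- profile$rates_per_min
  t_bar <- 60 / patient$neural_rate_bpm
  p_anom <- sum(rates) * t_bar / 60
  p_cough <- profile$cough_rate_per_min * t_bar / 60
  if (p_anom + p_cough > 0.9)
    stop("plan_session: infeasible profile (per-breath event probability > 0.9)")
  closed <- vent$sync_mode == "closed_loop_emulated"

  machine <- list()   # c(trig, cyc)
  pulses <- list()    # c(t0, ti, rel, amp)
  coughs <- numeric(0)
  truth <- list()     # c(time, kind-index, metric)
  kinds <- c("IE", "AT", "DB", "TD", "EC", "LC")
  add_truth <- function(time, kind, metric = NA_real_) {
    truth[[length(truth) + 1L]] <<- list(time, kind, metric)
  }
  prev_cyc <- -Inf; prev_ti <- 0.5
  t <- 0.5
  while (t < duration_s - 2.5) {
    T_k <- t_bar * exp(stats::rnorm(1, 0, patient$rate_variability_cv))
    T_k <- min(max(T_k, 0.55 * t_bar), 1.7 * t_bar)
    ti_k <- patient$neural_ti_s * exp(stats::rnorm(1, 0, 0.05))
    ti_k <- min(ti_k, 0.55 * T_k)
    amp <- patient$pmus_max_cmh2o * exp(stats::rnorm(1, 0, patient$pmus_variability_cv))
    u <- stats::runif(1)
    p <- rates * T_k / 60
    kind <- "normal"
    cum <- cumsum(p)
    hit <- which(u < cum)
    if (length(hit)) kind <- kinds[hit[1L]]

    if (kind == "DB") ti_k <- min(ti_k * 1.35, 0.65 * T_k)
    rel <- 0.5 * ti_k
    if (kind == "IE") amp <- amp * profile$ie_amp_frac
    obs <- t + effort_cross_time(ti_k, cfg_onset_frac)
    term <- t + ti_k + rel / 2

    if (kind == "IE") {
      pulses[[length(pulses) + 1L]] <- c(t, ti_k, rel, amp)
      add_truth(t, "IE")
      t <- t + T_k
      next
    }

    # realized trigger time
    if (kind == "TD") {
      rt <- stats::runif(1, profile$td_latency_range_ms[1L],
                         profile$td_latency_range_ms[2L]) / 1000
    } else if (closed) {
      rt <- rtrunc_norm(1, 0.045, 0.008, 0.025, 0.075)
    } else {
      p_ft <- patient$resistance_cmh2o_s_per_l * vent$flow_trigger_lpm / 60
      t_ft <- effort_cross_time(ti_k, p_ft / amp)
      valve <- rtrunc_norm(1, 0.035, 0.008, 0.018, 0.060)
      rt <- t_ft - effort_cross_time(ti_k, cfg_onset_frac) + valve
      rt <- max(rt, 0.005)
    }
    trig <- obs + rt
    # keep a physiologic expiratory gap after the previous cycle
    gap_min <- 0.6 * prev_ti + 0.12
    if (trig - prev_cyc < gap_min) {
      shift <- gap_min - (trig - prev_cyc)
      t <- t + shift; obs <- obs + shift; trig <- trig + shift; term <- term + shift
    }
    # trigger-phase ground truth from the realized response time
    rt_ms <- 1000 * rt
    if (rt_ms > 234) add_truth(trig, "IE", rt_ms)
    else if (rt_ms > 117) add_truth(trig, "TD", rt_ms)

    # realized cycle time(s)
    if (kind == "EC") {
      off <- stats::runif(1, profile$ec_offset_range_ms[1L],
                          profile$ec_offset_range_ms[2L]) / 1000
      cyc <- max(term - off, trig + 0.15)
      add_truth(cyc, "EC", 1000 * (term - cyc))
    } else if (kind == "LC") {
      off <- stats::runif(1, profile$lc_offset_range_ms[1L],
                          profile$lc_offset_range_ms[2L]) / 1000
      cyc <- min(term + off, trig + vent$max_ti_s)
      add_truth(cyc, "LC", -1000 * (cyc - term))
    } else if (kind == "DB") {
      ti1 <- max(0.45 * (term - trig), 0.28)
      cyc1 <- trig + ti1
      gap <- profile$db_gap_frac * ti1
      trig2 <- cyc1 + gap
      cyc2 <- min(max(term + stats::rnorm(1, 0, 0.03), trig2 + 0.15),
                  trig2 + vent$max_ti_s)
      machine[[length(machine) + 1L]] <- c(trig, cyc1)
      add_truth(trig2, "DB", gap / ti1)
      trig <- trig2; cyc <- cyc2
    } else {
      cyc <- term + max(min(stats::rnorm(1, 0, 0.025), 0.06), -0.06)
      cyc <- min(max(cyc, trig + 0.15), trig + vent$max_ti_s)
    }
    machine[[length(machine) + 1L]] <- c(trig, cyc)
    pulses[[length(pulses) + 1L]] <- c(t, ti_k, rel, amp)
    prev_cyc <- cyc; prev_ti <- cyc - trig
    t_next <- t + T_k

    if (kind == "AT") {
      ti1 <- cyc - trig
      at_trig <- cyc + 0.7 * ti1 + 0.05
      at_cyc <- at_trig + stats::runif(1, 0.45, 0.6)
      machine[[length(machine) + 1L]] <- c(at_trig, at_cyc)
      add_truth(at_trig, "AT")
      prev_cyc <- at_cyc; prev_ti <- at_cyc - at_trig
      t_next <- max(t_next, at_cyc + 0.55)
    }
    # cough artifacts only on otherwise-normal breaths: at most one injected
    # anomaly per breath keeps the ground truth unambiguous
    if (kind == "normal" && stats::runif(1) < p_cough) {
      coughs <- c(coughs, prev_cyc + 0.3)
      add_truth(prev_cyc + 0.3, "cough")
    }
    t <- t_next
  }
  machine <- do.call(rbind, machine)
  pulses <- do.call(rbind, pulses)
  truth <- if (length(truth)) {
    data.frame(time_s = vapply(truth, function(x) x[[1L]], numeric(1)),
               kind = vapply(truth, function(x) x[[2L]], character(1)),
               true_metric = vapply(truth, function(x) x[[3L]], numeric(1)))
  } else {
    data.frame(time_s = numeric(0), kind = character(0),
               true_metric = numeric(0))
  }
  truth <- truth[order(truth$time_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(machine = machine, pulses = pulses, coughs = coughs, truth = truth)
}

# ---------------------------------------------------------------------------
# Waveform synthesis from a plan (vectorized; exact exponential integrator
# for the linear single-compartment volume dynamics).
synth_waveforms <- function(plan, patient, vent, duration_s, sample_rate_hz,
                            leak_frac, gas) {
  rate <- sample_rate_hz
  dt <- 1 / rate
  n <- as.integer(round(duration_s * rate)) + 1L
  tt <- (seq_len(n) - 1L) * dt

  # Pmus: sum of raised-cosine pulses
  pmus <- numeric(n)
  if (!is.null(plan$pulses)) for (k in seq_len(nrow(plan$pulses))) {
    t0 <- plan$pulses[k, 1L]; ti <- plan$pulses[k, 2L]
    rel <- plan$pulses[k, 3L]; A <- plan$pulses[k, 4L]
    i0 <- max(1L, as.integer(floor(t0 * rate)) + 1L)
    i1 <- min(n, as.integer(ceiling((t0 + ti) * rate)) + 1L)
    i2 <- min(n, as.integer(ceiling((t0 + ti + rel) * rate)) + 1L)
    if (i1 > i0) {
      tr <- tt[i0:i1] - t0
      pmus[i0:i1] <- pmus[i0:i1] + A * sin(pmin(pmax(tr, 0), ti) * pi / (2 * ti))^2
    }
    if (i2 > i1) {
      tr <- tt[(i1 + 1L):i2] - t0 - ti
      pmus[(i1 + 1L):i2] <- pmus[(i1 + 1L):i2] +
        A * cos(pmin(pmax(tr, 0), rel) * pi / (2 * rel))^2
    }
  }

  # ventilator pressure: piecewise exponential toward PEEP / PEEP + PS
  peep <- vent$peep_cmh2o; ps <- vent$ps_cmh2o
  tau_rise <- max(vent$p_ramp_ms, 20) / 1000
  tau_fall <- 0.045
  paw_v <- rep(peep, n)
  in_insp <- rep(FALSE, n)
  if (!is.null(plan$machine) && nrow(plan$machine)) {
    sw <- data.frame(time = c(plan$machine[, 1L], plan$machine[, 2L]),
                     insp = rep(c(TRUE, FALSE), each = nrow(plan$machine)))
    sw <- sw[order(sw$time), , drop = FALSE]
    sw <- sw[sw$time < duration_s, , drop = FALSE]
    bounds <- c(as.integer(floor(sw$time * rate)) + 1L, n + 1L)
    p0 <- peep
    if (bounds[1L] > 1L) paw_v[1:(bounds[1L] - 1L)] <- peep
    for (s in seq_len(nrow(sw))) {
      a <- bounds[s]; b <- bounds[s + 1L] - 1L
      if (b < a) next
      target <- if (sw$insp[s]) peep + ps else peep
      tau <- if (sw$insp[s]) tau_rise else tau_fall
      seg_t <- pmax(tt[a:b] - sw$time[s], 0)
      paw_v[a:b] <- target + (p0 - target) * exp(-seg_t / tau)
      if (sw$insp[s]) in_insp[a:b] <- TRUE
      p0 <- paw_v[b]
    }
  }

  # volume / flow from the equation of motion
  r <- patient$resistance_cmh2o_s_per_l
  c_ <- patient$compliance_ml_per_cmh2o
  tau_rc <- r * c_ / 1000
  a_coef <- exp(-dt / tau_rc)
  p_net <- paw_v + pmus - peep
  v <- as.numeric(stats::filter((1 - a_coef) * c_ * p_net, a_coef,
                                method = "recursive"))
  flow_lpm <- (p_net - v / c_) / r * 60

  # recorded channels
  cough_flow <- numeric(n); cough_pes <- numeric(n)
  for (ct in plan$coughs) {
    i0 <- max(1L, as.integer(floor(ct * rate)) + 1L)
    i1 <- min(n, as.integer(ceiling((ct + 0.25) * rate)) + 1L)
    if (i1 > i0) {
      shp <- sin((tt[i0:i1] - ct) * pi / 0.25)^2
      cough_flow[i0:i1] <- cough_flow[i0:i1] + 25 * shp
      cough_pes[i0:i1] <- cough_pes[i0:i1] + 6 * shp
    }
  }
  ns <- patient$noise_sd
  flow_rec <- flow_lpm
  neg <- flow_rec < 0
  flow_rec[neg] <- flow_rec[neg] * (1 - leak_frac)
  flow_rec <- flow_rec + cough_flow + stats::rnorm(n, 0, ns$flow)
  aw_couple <- 0.25
  paw_rec <- paw_v - aw_couple * pmus * (1 - in_insp) + stats::rnorm(n, 0, ns$paw)
  pes_rec <- patient$pes_baseline_cmh2o +
    patient$chest_wall_elastance_cmh2o_per_ml * v - pmus + cough_pes +
    stats::rnorm(n, 0, ns$pes)

  # volume channel: integral of recorded flow, reset at each machine onset
  cum <- cumtrapz(flow_rec, dt) * 1000 / 60
  vol <- cum
  if (!is.null(plan$machine) && nrow(plan$machine)) {
    oi <- pmin(pmax(as.integer(floor(plan$machine[, 1L] * rate)) + 1L, 1L), n)
    oi <- sort(unique(oi))
    offs <- c(0, cum[oi])
    seg <- findInterval(seq_len(n), oi) + 1L
    vol <- cum - offs[seg]
  }

  # gas channels: slow AR(1) drift around the session means
  knot_dt <- 2
  nk <- max(2L, as.integer(duration_s / knot_dt) + 2L)
  ar1 <- function(nk, rho, sd) {
    x <- numeric(nk)
    x[1L] <- stats::rnorm(1, 0, sd)
    for (j in 2L:nk) x[j] <- rho * x[j - 1L] + stats::rnorm(1, 0, sd * sqrt(1 - rho^2))
    x
  }
  kt <- (seq_len(nk) - 1L) * knot_dt
  etco2 <- gas$etco2 + stats::approx(kt, ar1(nk, 0.9, 1.0), xout = tt,
                                     rule = 2)$y
  spo2 <- pmin(gas$spo2 + stats::approx(kt, ar1(nk, 0.9, 0.5), xout = tt,
                                        rule = 2)$y, 100)

  waveform_record(paw = paw_rec, flow = flow_rec, sample_rate_hz = rate,
                  volume = vol, pes = pes_rec, etco2 = etco2, spo2 = spo2)
}

# Ground-truth AI summary from a plan's truth log.
truth_ai_summary <- function(truth, n_machine) {
  ev <- truth$kind[truth$kind %in% EVENT_TYPES]
  ai <- compute_ai(ev, n_machine_breaths = n_machine)
  ai
}

#' Simulate one pressure-support session
#'
#' Generates a session of ventilator waveforms for one patient under one
#' synchronization mode, with asynchronies injected per the profile and a
#' ground-truth log of every event and its realized metric. Identical inputs
#' and seed give identical output; the caller's RNG state is untouched.
#'
#' @param patient A [patient_model()].
#' @param vent A [vent_settings()].
#' @param profile An [asynchrony_profile()].
#' @param duration_s Session length in seconds (>= 60).
#' @param seed Integer seed.
#' @param sample_rate_hz Sampling rate (default 50 Hz).
#' @param leak_frac Constant fractional inspiratory-volume loss applied to
#'   expiratory flow (default 0.06).
#' @param gas_means Session means for the gas channels,
#'   `list(etco2 = , spo2 = )` (defaults 43 mmHg, 96 percent).
#' @param comfort_mean Mean of the per-session Comfort-B draw (default 14).
#' @param waveforms If `FALSE`, plan events and summaries only (no waveform
#'   synthesis); used for large replicate studies at the summary level.
#' @return An object of class `sim_session`: `record` (a
#'   [waveform_record()], or `NULL` when `waveforms = FALSE`), `truth`
#'   (data frame `time_s`, `kind`, `true_metric`), `truth_ai` (an
#'   `ai_result` on the ground-truth events), `n_machine_breaths`,
#'   `comfort_b`, `gas_means`, `leak_frac`, plus the inputs.
#' @export
simulate_session <- function(patient, vent, profile, duration_s = 600,
                             seed = 1, sample_rate_hz = 50,
                             leak_frac = 0.06,
                             gas_means = list(etco2 = 43, spo2 = 96),
                             comfort_mean = 14,
                             waveforms = TRUE) {
  stopifnot(inherits(patient, "patient_model"),
            inherits(vent, "vent_settings"),
            inherits(profile, "asynchrony_profile"),
            duration_s >= 60)
  with_seed(seed, {
    plan <- plan_session(patient, vent, profile, duration_s)
    gas <- list(etco2 = gas_means$etco2 + stats::rnorm(1, 0, 1.0),
                spo2 = min(gas_means$spo2 + stats::rnorm(1, 0, 0.7), 99.5))
    comfort <- as.integer(round(rtrunc_norm(1, comfort_mean, 1.2, 6, 30)))
    n_machine <- if (is.null(plan$machine)) 0L else nrow(plan$machine)
    rec <- if (waveforms) {
      synth_waveforms(plan, patient, vent, duration_s, sample_rate_hz,
                      leak_frac, gas)
    }
    structure(list(
      record = rec, truth = plan$truth,
      machine_times = plan$machine,
      truth_ai = truth_ai_summary(plan$truth, n_machine),
      n_machine_breaths = n_machine,
      comfort_b = comfort, gas_means = gas, leak_frac = leak_frac,
      patient = patient, vent = vent, profile = profile,
      duration_s = duration_s, seed = seed
    ), class = "sim_session")
  })
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %.0f s, %s mode, %d machine breaths\n",
              x$duration_s, x$vent$sync_mode, x$n_machine_breaths))
  tb <- table(factor(x$truth$kind, levels = c(EVENT_TYPES, "cough")))
  cat("  injected:", paste(sprintf("%s %d", names(tb), tb), collapse = "  "), "\n")
  cat(sprintf("  ground-truth AI %.1f%%\n", x$truth_ai$ai_pct))
  invisible(x)
}

#' Ground-truth period summary of a simulated session
#'
#' One flat row of outcome values computed from the simulator's ground truth
#' (no waveform analysis): the AI family from the truth log, plus the
#' session's drawn gas means, leak and Comfort-B.
#'
#' @param session A `sim_session`.
#' @return A one-row data frame matching the pipeline's outcome columns.
#' @export
session_truth_row <- function(session) {
  ai <- session$truth_ai
  data.frame(
    ai_pct = ai$ai_pct, major_ai_pct = ai$major_ai_pct,
    minor_ai_pct = ai$minor_ai_pct,
    db_pct = 100 * ai$n_db / ai$denominator,
    at_pct = 100 * ai$n_at / ai$denominator,
    ie_pct = 100 * ai$n_ie / ai$denominator,
    td_pct = 100 * ai$n_td / ai$denominator,
    ec_pct = 100 * ai$n_ec / ai$denominator,
    lc_pct = 100 * ai$n_lc / ai$denominator,
    comfort_b = as.numeric(session$comfort_b),
    etco2_mmhg = session$gas_means$etco2,
    spo2_pct = session$gas_means$spo2,
    leak_pct = 100 * session$leak_frac
  )
}

#' Generate a two-arm crossover cohort
#'
#' Draws a pediatric patient population (lung-physiology profiles, neural
#' rates, effort amplitudes, leaks and ventilator settings centered on
#' typical invasively ventilated infants: PEEP 5, PS 8.5, respiratory rate
#' 28/min), builds conventional and closed-loop asynchrony profiles per
#' patient, simulates both measurement periods and assigns the intervention
#' order by block-of-four randomization. Per-patient and per-arm random
#' substreams are derived by counter-based splitting, so changing the cohort
#' size does not reshuffle existing patients.
#'
#' @param n_patients Number of patients (>= 2).
#' @param arm_effect Named per-type multiplicative rate factors for the
#'   closed-loop arm (defaults mirror large reductions in AT/DB/TD/EC, no
#'   change in IE, an increase in LC).
#' @param base_profile Conventional-arm [asynchrony_profile()]; the default
#'   targets a conventional-arm AI in the low teens.
#' @param duration_s Per-session length in seconds (default 600).
#' @param seed Root seed.
#' @param waveforms Synthesize waveforms (`TRUE`) or plan/summaries only.
#' @param cough_rate_per_min Cough-artifact rate added to both arms
#'   (default 0.2).
#' @param null_mode If `TRUE`, both arms are generated from the identical
#'   distribution (conventional synchronization, identical gas and comfort
#'   means) with independent draws — the exchangeable null used for type-I
#'   error calibration of the paired analysis. Default `FALSE`.
#' @return An object of class `crossover_cohort`: `patients` (list of
#'   per-patient records with `conventional` and `closed_loop`
#'   `sim_session`s and `order`), `n_patients`, `seed`, `arm_effect`.
#' @export
generate_crossover_cohort <- function(n_patients,
                                      arm_effect = c(IE = 1, AT = 0.33,
                                                     DB = 0.125, TD = 0.17,
                                                     EC = 0.07, LC = 2.6),
                                      base_profile = NULL,
                                      duration_s = 600,
                                      seed = 1,
                                      waveforms = TRUE,
                                      cough_rate_per_min = 0.2,
                                      null_mode = FALSE) {
  if (n_patients < 2) stop("generate_crossover_cohort: n_patients must be >= 2")
  if (is.null(base_profile)) {
    base_profile <- asynchrony_profile(
      rates_per_min = c(IE = 0.60, AT = 0.42, DB = 0.27, TD = 1.17,
                        EC = 0.95, LC = 0.24),
      cough_rate_per_min = cough_rate_per_min)
  }
  # block-of-four order randomization
  n_blocks <- ceiling(n_patients / 4)
  orders <- with_seed(derive_seed(seed, 0), {
    unlist(lapply(seq_len(n_blocks),
                  function(b) sample(rep(c("conventional_first",
                                           "closed_loop_first"), 2))))
  })[seq_len(n_patients)]

  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    ps_i <- with_seed(derive_seed(seed, i, 0), {
      prof_cat <- sample(c("mixed", "restrictive", "obstructive", "normal"),
                         1, prob = c(0.44, 0.28, 0.16, 0.12))
      base <- patient_model(physiology_profile = prof_cat)
      pm <- patient_model(
        physiology_profile = prof_cat,
        resistance_cmh2o_s_per_l = base$resistance_cmh2o_s_per_l *
          exp(stats::rnorm(1, 0, 0.15)),
        compliance_ml_per_cmh2o = base$compliance_ml_per_cmh2o *
          exp(stats::rnorm(1, 0, 0.15)),
        pmus_max_cmh2o = stats::runif(1, 7, 11),
        neural_rate_bpm = rtrunc_norm(1, 28, 5, 18, 42)
      )
      pm$neural_ti_s <- min(max(0.33 * 60 / pm$neural_rate_bpm + 0.02, 0.35), 1.0)
      # physician-tailored flow trigger: scaled down for high-resistance
      # patients (whose inspiratory flow builds slowly) so that triggering
      # stays responsive across lung physiologies
      ft <- stats::runif(1, 0.5, 1) * 45 / pm$resistance_cmh2o_s_per_l
      vs <- vent_settings(ps_cmh2o = stats::runif(1, 6.5, 10.5),
                          peep_cmh2o = 5,
                          flow_trigger_lpm = min(max(ft, 0.3), 1.2))
      jit <- exp(stats::rnorm(6, 0, 0.25))
      leak <- stats::runif(1, 0.04, 0.08)
      list(pm = pm, vs = vs, jit = jit, leak = leak)
    })
    conv_prof <- base_profile
    conv_prof$rates_per_min <- conv_prof$rates_per_min * ps_i$jit
    cl_prof <- if (null_mode) conv_prof else scale_profile(conv_prof, arm_effect)
    vs_cl <- ps_i$vs
    if (!null_mode) vs_cl$sync_mode <- "closed_loop_emulated"
    cl_gas <- if (null_mode) list(etco2 = 43, spo2 = 96) else
      list(etco2 = 42, spo2 = 96)
    conv <- simulate_session(ps_i$pm, ps_i$vs, conv_prof, duration_s,
                             seed = derive_seed(seed, i, 1),
                             leak_frac = ps_i$leak,
                             gas_means = list(etco2 = 43, spo2 = 96),
                             comfort_mean = 14, waveforms = waveforms)
    cl <- simulate_session(ps_i$pm, vs_cl, cl_prof, duration_s,
                           seed = derive_seed(seed, i, 2),
                           leak_frac = ps_i$leak,
                           gas_means = cl_gas,
                           comfort_mean = if (null_mode) 14 else 13,
                           waveforms = waveforms)
    patients[[i]] <- list(patient_id = sprintf("P%02d", i),
                          model = ps_i$pm, vent = ps_i$vs,
                          order = orders[i],
                          conventional = conv, closed_loop = cl)
  }
  structure(list(patients = patients, n_patients = n_patients, seed = seed,
                 arm_effect = arm_effect, duration_s = duration_s),
            class = "crossover_cohort")
}

#' @export
print.crossover_cohort <- function(x, ...) {
  tb <- table(vapply(x$patients, `[[`, character(1), "order"))
  cat(sprintf("<crossover_cohort> %d patients, %.0f-s sessions, seed %d\n",
              x$n_patients, x$duration_s, x$seed))
  cat("  order:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth outcome summaries for a cohort
#'
#' Stacks [session_truth_row()] for every patient and arm into the long
#' format consumed by [analyze_crossover()].
#'
#' @param cohort A `crossover_cohort`.
#' @return Data frame with `patient_id`, `arm` and the outcome columns.
#' @export
cohort_truth_summaries <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    rbind(cbind(data.frame(patient_id = p$patient_id, arm = "conventional",
                           stringsAsFactors = FALSE),
                session_truth_row(p$conventional)),
          cbind(data.frame(patient_id = p$patient_id, arm = "closed_loop",
                           stringsAsFactors = FALSE),
                session_truth_row(p$closed_loop)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
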