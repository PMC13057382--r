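#' Multichannel ventilator waveform record
#'
#' The container every analysis stage consumes: uniformly sampled airway
#' pressure and flow, plus optional volume, esophageal pressure, EtCO2 and
#' SpO2 channels, an artifact mask and free-form metadata. Time is measured
#' in seconds from the start of the record; sample `k` (1-based) sits at
#' `t0_s + (k - 1) / sample_rate_hz`.
#'
#' Units are fixed: cmH2O for pressures, L/min for flow (inspiratory
#' positive), mL for volume, mmHg for EtCO2, percent for SpO2.
#'
#' @param paw Airway pressure series (cmH2O); must be finite.
#' @param flow Flow series (L/min, inspiratory positive); must be finite.
#' @param sample_rate_hz Sampling rate (Hz), default 50 (high-frequency
#'   ventilator acquisition).
#' @param t0_s Time of the first sample (s), default 0.
#' @param volume Volume series (mL); derived by cumulative trapezoidal
#'   integration of flow when absent.
#' @param pes Optional esophageal pressure series (cmH2O).
#' @param etco2 Optional end-tidal CO2 series (mmHg).
#' @param spo2 Optional pulse-oximetry series (percent).
#' @param artifact_mask Logical series, `TRUE` = excluded from analysis;
#'   defaults to all `FALSE`.
#' @param meta Named list of free-form metadata (patient id, arm, period...).
#'
#' @return An object of class `waveform_record`.
#' @examples
#' rec <- waveform_record(paw = rep(5, 100), flow = rep(0, 100))
#' rec$sample_rate_hz
#' @export
waveform_record <- function(paw, flow, sample_rate_hz = 50, t0_s = 0,
                            volume = NULL, pes = NULL, etco2 = NULL,
                            spo2 = NULL, artifact_mask = NULL, meta = list()) {
  n <- length(paw)
  if (n < 2L) stop("waveform_record: channels must have length >= 2")
  if (length(flow) != n) stop("waveform_record: channel lengths differ")
  if (!all(is.finite(paw))) stop("waveform_record: paw must be finite everywhere")
  if (!all(is.finite(flow))) stop("waveform_record: flow must be finite everywhere")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("waveform_record: sample_rate_hz must be positive")
  for (ch in list(volume = volume, pes = pes, etco2 = etco2, spo2 = spo2)) {
    if (!is.null(ch) && length(ch) != n)
      stop("waveform_record: channel lengths differ")
  }
  if (is.null(volume)) volume <- cumtrapz(flow, 1 / sample_rate_hz) * 1000 / 60
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n)
  if (length(artifact_mask) != n)
    stop("waveform_record: artifact_mask length differs from channels")
  structure(list(
    sample_rate_hz = as.numeric(sample_rate_hz),
    t0_s = as.numeric(t0_s),
    paw = as.numeric(paw),
    flow = as.numeric(flow),
    volume = as.numeric(volume),
    pes = if (is.null(pes)) NULL else as.numeric(pes),
    etco2 = if (is.null(etco2)) NULL else as.numeric(etco2),
    spo2 = if (is.null(spo2)) NULL else as.numeric(spo2),
    artifact_mask = as.logical(artifact_mask),
    meta = meta
  ), class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$paw)
  opt <- c("pes", "etco2", "spo2")
  present <- opt[!vapply(x[opt], is.null, logical(1))]
  cat(sprintf("<waveform_record> %d samples @ %g Hz (%.1f s)\n",
              n, x$sample_rate_hz, (n - 1) / x$sample_rate_hz))
  cat("  channels: paw, flow, volume",
      if (length(present)) paste0(", ", paste(present, collapse = ", ")) else "",
      "\n", sep = "")
  cat(sprintf("  masked samples: %d\n", sum(x$artifact_mask)))
  invisible(x)
}

#' Duration of a waveform record in seconds
#' @param record A [waveform_record()].
#' @return Implied duration `(n - 1) / sample_rate_hz`.
#' @export
record_duration <- function(record) {
  (length(record$paw) - 1L) / record$sample_rate_hz
}

# Time vector of a record (seconds from t0).
record_times <- function(record) {
  record$t0_s + (seq_along(record$paw) - 1L) / record$sample_rate_hz
}

.wf_columns <- c(time_s = "time_s", paw = "paw_cmh2o", flow = "flow_lpm",
                 volume = "vol_ml", pes = "pes_cmh2o", etco2 = "etco2_mmhg",
                 spo2 = "spo2_pct")

#' Read a waveform record from delimited text
#'
#' The waveform file format is UTF-8 comma-separated text with a header row
#' naming at least `time_s`, `paw_cmh2o` and `flow_lpm`; optional columns
#' `vol_ml`, `pes_cmh2o`, `etco2_mmhg` and `spo2_pct` populate the
#' corresponding channels. Lines starting with `#` carry metadata as
#' `# key: value`.
#'
#' The sample rate is inferred from the median time step and the time base is
#' checked for uniformity (maximum deviation below 10 percent of the step).
#'
#' @param source Path to the file (or a connection readable by `readLines`).
#' @param strict If `TRUE` (default), a non-uniform time base beyond
#'   tolerance is an error; if `FALSE`, a warning.
#' @return A [waveform_record()].
#' @seealso [write_waveform()]
#' @export
read_waveform <- function(source, strict = TRUE) {
  lines <- readLines(source, warn = FALSE)
  if (!length(lines)) stop("read_waveform: empty file")
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("read_waveform: no data rows")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time_s", "paw_cmh2o", "flow_lpm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_waveform: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  tt <- df$time_s
  if (length(tt) < 2L) stop("read_waveform: fewer than 2 samples")
  steps <- diff(tt)
  step <- stats::median(steps)
  if (!is.finite(step) || step <= 0)
    stop("read_waveform: non-increasing time column")
  dev <- max(abs(steps - step))
  if (dev >= 0.1 * step) {
    msg <- sprintf("read_waveform: non-uniform time base (max deviation %.3g of step %.3g)",
                   dev, step)
    if (strict) stop(msg) else warning(msg)
  }
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ml))[[1L]]
    if (length(m) == 3L) {
      val <- trimws(m[3L])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2L])]] <- if (!is.na(num)) num else val
    }
  }
  waveform_record(
    paw = df$paw_cmh2o, flow = df$flow_lpm,
    sample_rate_hz = 1 / step, t0_s = 0,
    volume = df[["vol_ml"]], pes = df[["pes_cmh2o"]],
    etco2 = df[["etco2_mmhg"]], spo2 = df[["spo2_pct"]],
    meta = meta
  )
}

#' Write a waveform record to delimited text
#'
#' Writes the format read by [read_waveform()]; numeric values are printed
#' with 17 significant digits so that a read/write round trip preserves every
#' channel exactly.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  cols <- list(time_s = record_times(record) - record$t0_s,
               paw_cmh2o = record$paw, flow_lpm = record$flow,
               vol_ml = record$volume, pes_cmh2o = record$pes,
               etco2_mmhg = record$etco2, spo2_pct = record$spo2)
  cols <- cols[!vapply(cols, is.null, logical(1))]
  header <- paste(names(cols), collapse = ",")
  meta <- record$meta
  meta_lines <- if (length(meta))
    sprintf("# %s: %s", names(meta),
            vapply(meta, function(v) paste(format(v, digits = 17), collapse = " "),
                   character(1)))
  else character(0)
  mat <- vapply(cols, function(v) sprintf("%.17g", v),
                character(length(cols[[1L]])))
  rows <- apply(mat, 1L, paste, collapse = ",")
  writeLines(c(meta_lines, header, rows), path)
  invisible(path)
}

#' Integrate flow over an index window
#'
#' Trapezoidal integral of a flow series (L/min) between two sample indices,
#' returned in mL (1 L/min = 1000/60 mL/s).
#'
#' @param flow Flow series (L/min).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param start_index,end_index 1-based index window, `start <= end`.
#' @return Integrated volume in mL (signed).
#' @examples
#' integrate_volume(rep(60, 51), 50, 1, 51)  # 60 L/min for 1 s -> 1000 mL
#' @export
integrate_volume <- function(flow, sample_rate_hz, start_index = 1L,
                             end_index = length(flow)) {
  n <- length(flow)
  if (start_index < 1L || end_index > n || start_index > end_index)
    stop("integrate_volume: index window out of range")
  if (start_index == end_index) return(0)
  w <- flow[start_index:end_index]
  sum((w[-length(w)] + w[-1L]) / 2) / sample_rate_hz * 1000 / 60
}

#' Breath-by-breath leak percentage
#'
#' Leak around the endotracheal tube, defined from per-breath volumes as
#' `100 * (v_insp - v_exp) / v_insp`, clamped to `[0, 100]` (an expiratory
#' volume exceeding the inspiratory one reflects measurement noise, not a
#' negative leak).
#'
#' @param v_insp Inspired volume (mL), must be positive.
#' @param v_exp Expired volume (mL), non-negative.
#' @return Leak in percent. Vectorized over both arguments.
#' @examples
#' compute_breath_leak(100, 94)  # 6
#' @export
compute_breath_leak <- function(v_insp, v_exp) {
  if (any(v_insp <= 0)) stop("compute_breath_leak: v_insp must be positive")
  if (any(v_exp < 0)) stop("compute_breath_leak: v_exp must be non-negative")
  pmin(pmax(100 * (v_insp - v_exp) / v_insp, 0), 100)
}

#' Mask cough and active-expiration artifacts
#'
#' Sets the artifact mask over windows where (a) expiratory-phase flow shows
#' positive spikes exceeding `cfg$cough_flow_spike_lpm` (outside machine
#' pressurization), or (b) the esophageal pressure, if present, shows
#' positive transients exceeding `cfg$active_exp_pes_cmh2o` above its rolling
#' baseline. Masked windows are padded by `cfg$artifact_pad_s` on each side
#' and are excluded from all downstream event counting (numerator and
#' denominator). Masking is idempotent and never clears existing mask bits.
#'
#' @param record A [waveform_record()].
#' @param cfg A [classifier_config()].
#' @return The record with an updated `artifact_mask`.
#' @export
mask_artifacts <- function(record, cfg = classifier_config()) {
  stopifnot(inherits(record, "waveform_record"))
  cfg <- as_classifier_config(cfg)
  rate <- record$sample_rate_hz
  lev <- estimate_paw_levels(record$paw)
  in_insp <- record$paw > lev$peep + 0.4 * max(lev$ps, 1)
  # dilate the pressurization indicator: flow leads pressure by tens of ms
  # at (re-)triggering, which must not read as an expiratory spike
  k <- as.integer(round(0.25 * rate)) * 2L + 1L
  in_insp <- as.numeric(stats::filter(as.numeric(in_insp), rep(1, k),
                                      sides = 2L))
  in_insp[is.na(in_insp)] <- 0
  in_insp <- as.logical(in_insp > 0)
  spike <- record$flow > cfg$cough_flow_spike_lpm & !in_insp
  if (!is.null(record$pes)) {
    kb <- as.integer(cfg$pes_baseline_win_s * rate)
    if (kb %% 2L == 0L) kb <- kb + 1L
    base <- if (length(record$pes) > kb) {
      as.numeric(stats::runmed(record$pes, kb, endrule = "median"))
    } else rep(stats::median(record$pes), length(record$pes))
    spike <- spike | (record$pes - base > cfg$active_exp_pes_cmh2o)
  }
  if (any(spike)) {
    pad <- as.integer(round(cfg$artifact_pad_s * rate))
    runs <- true_runs(spike)
    mask <- record$artifact_mask
    for (r in seq_len(nrow(runs))) {
      a <- max(1L, runs[r, 1L] - pad)
      b <- min(length(mask), runs[r, 2L] + pad)
      mask[a:b] <- TRUE
    }
    record$artifact_mask <- mask
  }
  record
}

#' Write classifier events to delimited text
#'
#' Event files are comma-separated with header
#' `time_s,breath_index,type,severity,metric_value,metric_units`.
#'
#' @param events An event data frame as returned by [classify_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    time_s = events$time_s,
    breath_index = ifelse(is.na(events$breath_index), "", events$breath_index),
    type = events$type,
    severity = events$severity,
    metric_value = events$metric_value,
    metric_units = events$metric_units,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a classifier event file
#' @param path Path written by [write_events()].
#' @return An event data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$breath_index <- suppressWarnings(as.integer(df$breath_index))
  df
}
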