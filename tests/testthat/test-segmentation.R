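test_that("fit_passive_decay recovers an exact exponential and rejects others", {
  rate <- 50
  tt <- seq(0, 1.2, by = 1 / rate)
  cfg <- classifier_config()

  fit <- fit_passive_decay(-20 * exp(-tt / 0.3), rate, cfg)
  expect_true(fit$is_passive)
  expect_equal(fit$tau_s, 0.3, tolerance = 0.01)
  expect_gte(fit$r_squared, 0.999)

  # constant flow has no decay
  set.seed(1)
  fit2 <- fit_passive_decay(rep(-10, 40) + rnorm(40, 0, 0.05), rate, cfg)
  expect_false(fit2$is_passive)
  expect_lt(fit2$r_squared, 0.5)

  # an early notch toward zero breaks log-linearity
  notch <- -20 * exp(-tt / 0.3)
  mid <- tt >= 0.2 & tt <= 0.45
  notch[mid] <- notch[mid] + 4 * sin((tt[mid] - 0.2) * pi / 0.25)^2
  fit3 <- fit_passive_decay(notch, rate, cfg)
  expect_false(fit3$is_passive)

  # too few usable samples -> failed fit
  fit4 <- fit_passive_decay(c(-3, -2.5, -2.2), rate, cfg)
  expect_false(fit4$is_passive)
  expect_true(is.na(fit4$tau_s))
})

test_that("detect_breaths finds clean simulated breaths near ground truth", {
  pm <- patient_model(neural_rate_bpm = 20, rate_variability_cv = 0)
  vs <- vent_settings()
  s <- simulate_session(pm, vs, asynchrony_profile(rates_per_min = rep(0, 6)),
                        duration_s = 126, seed = 10)
  br <- detect_breaths(s$record)
  expect_equal(nrow(br), s$n_machine_breaths)
  # every onset within 40 ms of the simulator's trigger time
  err <- br$onset_time_s - s$machine_times[, 1]
  expect_lt(max(abs(err)), 0.040)
  expect_true(all(br$ti_s > 0))
  expect_true(all(br$te_s >= 0))
  expect_true(all(br$onset_time_s < br$cycle_time_s))
  expect_true(all(br$cycle_time_s < br$end_time_s))
})

test_that("detect_breaths handles degenerate and constructed inputs", {
  # all-zero flow, flat pressure: no breaths
  rec <- waveform_record(paw = rep(5, 1000), flow = rep(0, 1000))
  expect_equal(nrow(detect_breaths(rec)), 0)

  # one isolated square breath: Ti recovered within 40 ms
  rec2 <- square_breath_record(ti_s = 1)
  br <- detect_breaths(rec2)
  expect_equal(nrow(br), 1)
  expect_equal(br$ti_s, 1, tolerance = 0.04)
})

test_that("segmentation is translation-invariant", {
  pm <- patient_model()
  vs <- vent_settings()
  s <- simulate_session(pm, vs, asynchrony_profile(rates_per_min = rep(0, 6)),
                        duration_s = 90, seed = 12)
  rec <- s$record
  k <- 100L  # 2 s
  shift <- function(x) if (is.null(x)) NULL else x[-seq_len(k)]
  rec2 <- waveform_record(paw = shift(rec$paw), flow = shift(rec$flow),
                          sample_rate_hz = rec$sample_rate_hz,
                          volume = shift(rec$volume), pes = shift(rec$pes))
  b1 <- detect_breaths(rec)
  b2 <- detect_breaths(rec2)
  # compare interior breaths (the first may straddle the cut)
  o1 <- b1$onset_time_s[b1$onset_time_s > k / rec$sample_rate_hz + 1]
  o2 <- b2$onset_time_s[b2$onset_time_s > 1] + k / rec$sample_rate_hz
  m <- min(length(o1), length(o2))
  expect_gt(m, 10)
  expect_lt(max(abs(tail(o1, m) - tail(o2, m))), 0.005)
})

test_that("detect_efforts recovers raised-cosine efforts and their timing", {
  fx <- pes_effort_record(amp = 8, ti = 0.7, rel = 0.35)
  ef <- detect_efforts(fx$record)
  expect_equal(nrow(ef), 1)
  expect_equal(ef$amplitude_cmh2o, 8, tolerance = 0.3)
  # termination at the analytic midpoint of the rapid post-nadir rise
  expect_equal(ef$termination_time_s, fx$termination, tolerance = 0.04)
  # the detected onset sits at the onset-fraction crossing, slightly after
  # the true neural onset
  expect_lt(abs(ef$onset_time_s - fx$onset), 0.25)
  expect_gt(ef$onset_time_s, fx$onset)
  expect_true(ef$onset_time_s < ef$nadir_time_s)
  expect_true(ef$nadir_time_s < ef$termination_time_s)

  # flat Pes with noise below threshold: no efforts
  set.seed(3)
  rec <- waveform_record(paw = rep(5, 500), flow = rep(0, 500),
                         pes = -3 + rnorm(500, 0, 0.1))
  expect_equal(nrow(detect_efforts(rec)), 0)

  # Pes absent is a capability error
  rec2 <- waveform_record(paw = rep(5, 500), flow = rep(0, 500))
  expect_error(detect_efforts(rec2), "pes")
})

test_that("two efforts two seconds apart stay separate", {
  rate <- 50
  tt <- (seq_len(10 * rate) - 1) / rate
  pmus <- numeric(length(tt))
  for (t0 in c(3, 5)) {
    rise <- tt >= t0 & tt <= t0 + 0.7
    pmus[rise] <- pmus[rise] + 8 * sin((tt[rise] - t0) * pi / 1.4)^2
    fall <- tt > t0 + 0.7 & tt <= t0 + 1.05
    pmus[fall] <- pmus[fall] + 8 * cos((tt[fall] - t0 - 0.7) * pi / 0.7)^2
  }
  rec <- waveform_record(paw = rep(5, length(tt)), flow = rep(0, length(tt)),
                         pes = -3 - pmus)
  ef <- detect_efforts(rec)
  expect_equal(nrow(ef), 2)
  expect_equal(ef$onset_time_s, sort(ef$onset_time_s))
  expect_equal(diff(ef$onset_time_s), 2, tolerance = 0.1)
})

test_that("match_efforts implements the windowed greedy contract", {
  cfg <- classifier_config()
  br <- data.frame(onset_time_s = 10.050)
  ef <- data.frame(onset_time_s = 10.000)
  m <- match_efforts(br, ef, cfg)
  expect_equal(nrow(m$links), 1)
  expect_equal(m$links$response_time_ms, 50, tolerance = 1e-9)

  # effort with no breath in window -> IE candidate
  m2 <- match_efforts(data.frame(onset_time_s = 12), data.frame(onset_time_s = 10), cfg)
  expect_equal(nrow(m2$links), 0)
  expect_equal(m2$unmatched_efforts, 1L)
  expect_equal(m2$unmatched_breaths, 1L)

  # two efforts 400 ms apart, one breath: earlier effort wins
  m3 <- match_efforts(data.frame(onset_time_s = 10.5),
                      data.frame(onset_time_s = c(10.0, 10.4)), cfg)
  expect_equal(m3$links$effort_index, 1L)
  expect_equal(m3$unmatched_efforts, 2L)
})

test_that("greedy matching attains the brute-force maximum cardinality", {
  cfg <- classifier_config()
  set.seed(42)
  for (i in 1:40) {
    nb <- sample(0:6, 1); ne <- sample(0:6, 1)
    br <- data.frame(onset_time_s = sort(runif(nb, 0, 4)))
    ef <- data.frame(onset_time_s = sort(runif(ne, 0, 4)))
    m <- match_efforts(br, ef, cfg)
    best <- brute_force_max_matching(br$onset_time_s, ef$onset_time_s, cfg)
    expect_equal(nrow(m$links), best,
                 info = sprintf("instance %d (nb=%d, ne=%d)", i, nb, ne))
  }
})
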