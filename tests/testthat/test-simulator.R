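test_that("constructors validate their physiological invariants", {
  expect_error(patient_model(neural_rate_bpm = 30, neural_ti_s = 2.5))
  expect_error(vent_settings(ets_pct = 0))
  expect_error(asynchrony_profile(td_latency_range_ms = c(50, 200)))
  expect_error(asynchrony_profile(ec_offset_range_ms = c(50, 200)))
  pm <- patient_model("obstructive")
  expect_equal(pm$resistance_cmh2o_s_per_l, 60)
  expect_equal(pm$compliance_ml_per_cmh2o, 14)
})

test_that("simulation is deterministic and leaves the caller RNG alone", {
  pm <- patient_model(); vs <- vent_settings(); pr <- asynchrony_profile()
  set.seed(777)
  before <- runif(1)
  set.seed(777)
  s1 <- simulate_session(pm, vs, pr, duration_s = 120, seed = 9)
  after <- runif(1)
  expect_identical(before, after)  # RNG state restored around the simulation
  s2 <- simulate_session(pm, vs, pr, duration_s = 120, seed = 9)
  expect_identical(s1$record$paw, s2$record$paw)
  expect_identical(s1$record$flow, s2$record$flow)
  expect_identical(s1$record$pes, s2$record$pes)
  expect_identical(s1$truth, s2$truth)
})

test_that("a zero-injection session is clean end to end", {
  pm <- patient_model(); vs <- vent_settings()
  s <- simulate_session(pm, vs, asynchrony_profile(rates_per_min = rep(0, 6)),
                        duration_s = 300, seed = 77)
  expect_equal(nrow(s$truth), 0)
  expect_equal(s$truth_ai$ai_pct, 0)
  res <- classify_record(s$record)
  ai <- compute_ai(res$events, sum(!res$breaths$masked))
  expect_equal(ai$ai_pct, 0)
})

test_that("infeasible injection rates are refused", {
  pm <- patient_model(); vs <- vent_settings()
  pr <- asynchrony_profile(rates_per_min = c(IE = 10, AT = 10, DB = 10,
                                             TD = 10, EC = 10, LC = 10))
  expect_error(simulate_session(pm, vs, pr, duration_s = 120, seed = 1),
               "infeasible")
})

test_that("injected IE counts scale with the requested rate", {
  pm <- patient_model(); vs <- vent_settings()
  pr <- asynchrony_profile(rates_per_min = c(IE = 5, AT = 0, DB = 0, TD = 0,
                                             EC = 0, LC = 0))
  s <- simulate_session(pm, vs, pr, duration_s = 1200, seed = 13)
  n_ie <- sum(s$truth$kind == "IE")
  # 5/min over 20 min = 100 expected, Poisson-scale variation
  expect_gt(n_ie, 70)
  expect_lt(n_ie, 130)
  expect_equal(s$truth_ai$n_ie, n_ie)

  # monotonicity in the rate (averaged over seeds)
  mean_count <- function(rate_ie) {
    mean(vapply(1:6, function(sd) {
      pr <- asynchrony_profile(rates_per_min = c(IE = rate_ie, AT = 0, DB = 0,
                                                 TD = 0, EC = 0, LC = 0))
      sum(simulate_session(pm, vs, pr, duration_s = 120,
                           seed = sd, waveforms = FALSE)$truth$kind == "IE")
    }, numeric(1)))
  }
  expect_lte(mean_count(0.5), mean_count(2))
  expect_lte(mean_count(2), mean_count(5))
})

test_that("waveforms respect the mechanics: volume conservation and Paw bounds", {
  pm <- patient_model(noise_sd = list(paw = 0, flow = 0, pes = 0))
  vs <- vent_settings()
  s <- simulate_session(pm, vs, asynchrony_profile(rates_per_min = rep(0, 6)),
                        duration_s = 120, seed = 14, leak_frac = 0)
  br <- detect_breaths(s$record)
  # steady-state breaths conserve volume within 1 percent when leak is off
  mid <- br[5:(nrow(br) - 2), ]
  leak <- compute_breath_leak(mid$v_insp_ml, mid$v_exp_ml)
  expect_lt(stats::median(leak), 1)
  # Paw stays within [PEEP - 2, PEEP + PS + 2] on a clean session
  expect_gte(min(s$record$paw), vs$peep_cmh2o - 2)
  expect_lte(max(s$record$paw), vs$peep_cmh2o + vs$ps_cmh2o + 2)
})

test_that("the injected leak fraction is recovered breath by breath", {
  pm <- patient_model()
  vs <- vent_settings()
  s <- simulate_session(pm, vs, asynchrony_profile(rates_per_min = rep(0, 6)),
                        duration_s = 300, seed = 15, leak_frac = 0.06)
  br <- detect_breaths(s$record)
  mid <- br[5:(nrow(br) - 2), ]
  leak <- mean(compute_breath_leak(mid$v_insp_ml, mid$v_exp_ml))
  expect_equal(leak, 6, tolerance = 0.5)
})

test_that("the emulated closed-loop arm is synchronous by construction", {
  pm <- patient_model()
  vs <- vent_settings(sync_mode = "closed_loop_emulated")
  s <- simulate_session(pm, vs, asynchrony_profile(rates_per_min = rep(0, 6)),
                        duration_s = 300, seed = 16)
  cfg <- classifier_config()
  br <- detect_breaths(s$record, cfg)
  ef <- detect_efforts(s$record, cfg)
  m <- match_efforts(br, ef, cfg)
  expect_equal(length(m$unmatched_breaths), 0)
  expect_true(all(pmax(m$links$response_time_ms, 0) < 117))
  offs <- 1000 * (ef$termination_time_s[m$links$effort_index] -
                    br$cycle_time_s[m$links$breath_index])
  expect_true(all(abs(offs) < 100))
})

test_that("crossover cohorts randomize order in blocks of four", {
  expect_error(generate_crossover_cohort(0), "n_patients")
  expect_error(generate_crossover_cohort(1), "n_patients")
  co <- generate_crossover_cohort(25, duration_s = 60, seed = 5,
                                  waveforms = FALSE)
  orders <- vapply(co$patients, `[[`, character(1), "order")
  tab <- table(orders)
  expect_true(all(sort(as.integer(tab)) == c(12, 13)))
  # block structure: every aligned block of four is balanced 2/2
  for (b in 1:6) {
    blk <- orders[(4 * b - 3):(4 * b)]
    expect_equal(sum(blk == "conventional_first"), 2)
  }
})

test_that("per-patient substreams are stable under cohort growth", {
  co8 <- generate_crossover_cohort(8, duration_s = 60, seed = 6,
                                   waveforms = FALSE)
  co12 <- generate_crossover_cohort(12, duration_s = 60, seed = 6,
                                    waveforms = FALSE)
  for (i in 1:8) {
    expect_identical(co8$patients[[i]]$model, co12$patients[[i]]$model)
    expect_identical(co8$patients[[i]]$conventional$truth,
                     co12$patients[[i]]$conventional$truth)
  }
})

test_that("identity arm effects in null mode give a null paired AI difference", {
  diffs <- vapply(1:30, function(sd) {
    co <- generate_crossover_cohort(10, duration_s = 300, seed = sd,
                                    waveforms = FALSE, null_mode = TRUE)
    tr <- cohort_truth_summaries(co)
    median(tr$ai_pct[tr$arm == "closed_loop"] -
             tr$ai_pct[tr$arm == "conventional"])
  }, numeric(1))
  # the median of per-seed median differences is near zero
  expect_lt(abs(median(diffs)), 1)
  expect_gt(mean(diffs > 0), 0.2)
  expect_gt(mean(diffs < 0), 0.2)
})
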