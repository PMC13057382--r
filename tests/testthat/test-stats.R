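test_that("normality assessment routes by Shapiro-Wilk plus moments", {
  set.seed(100)
  a <- assess_normality(rnorm(200))
  expect_equal(a$route, "parametric")
  expect_true(a$sw_p >= 0 && a$sw_p <= 1)

  b <- assess_normality(rexp(200))
  expect_equal(b$route, "nonparametric")
  expect_gt(b$skewness, 1)

  expect_error(assess_normality(rep(1, 10)), "constant")
  expect_error(assess_normality(c(1, 2)), "at least 3")
})

test_that("Hodges-Lehmann estimate is the median Walsh average", {
  # d = {1,2,3}: Walsh averages {1, 1.5, 2, 2, 2.5, 3} -> estimate 2
  hl <- hodges_lehmann_ci(c(1, 2, 3))
  expect_equal(hl$estimate, 2)

  # sign equivariance: negation negates and swaps the interval
  set.seed(7)
  d <- rnorm(15, 1)
  h1 <- hodges_lehmann_ci(d)
  h2 <- hodges_lehmann_ci(-d)
  expect_equal(h2$estimate, -h1$estimate)
  expect_equal(h2$ci_low, -h1$ci_high)
  expect_equal(h2$ci_high, -h1$ci_low)

  # location-shift equivariance
  h3 <- hodges_lehmann_ci(d + 10)
  expect_equal(h3$estimate, h1$estimate + 10)

  # estimate lies within the data range
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1))
    h <- hodges_lehmann_ci(x)
    expect_gte(h$estimate, min(x))
    expect_lte(h$estimate, max(x))
    expect_lte(h$ci_low, h$estimate)
    expect_gte(h$ci_high, h$estimate)
  }
})

test_that("Hodges-Lehmann interval agrees with the signed-rank reference", {
  set.seed(11)
  for (i in 1:10) {
    d <- rnorm(sample(8:30, 1), mean = 0.5)
    h <- hodges_lehmann_ci(d, 0.95)
    w <- suppressWarnings(stats::wilcox.test(d, conf.int = TRUE,
                                             conf.level = 0.95, exact = TRUE))
    expect_equal(h$estimate, unname(w$estimate), tolerance = 1e-9)
    expect_equal(h$ci_low, w$conf.int[1], tolerance = 1e-9)
    expect_equal(h$ci_high, w$conf.int[2], tolerance = 1e-9)
  }
  # exact-rank endpoints near the normal approximation at moderate n
  set.seed(12)
  d <- rnorm(40, 0.3)
  walsh <- sort(outer(d, d, "+")[upper.tri(diag(40), diag = TRUE)] / 2)
  exact_lo <- hodges_lehmann_ci(d)$ci_low
  mu <- length(walsh) / 2
  sigma <- sqrt(40 * 41 * 81 / 24)
  approx_lo <- walsh[max(1, floor(mu + qnorm(0.025) * sigma))]
  gap <- abs(which.min(abs(walsh - exact_lo)) -
               which.min(abs(walsh - approx_lo)))
  expect_lte(gap, 15)  # within a handful of order statistics
})

test_that("paired_compare routes, estimates and degenerates correctly", {
  set.seed(20)
  a <- rnorm(20)
  # identical arms: estimate 0, p = 1
  r0 <- paired_compare(a, a)
  expect_equal(r0$point_estimate, 0)
  expect_equal(r0$p_two_sided, 1)
  expect_true(r0$degenerate)

  # constant shift: Hodges-Lehmann recovers it exactly on the
  # nonparametric route, the mean on the parametric route
  aexp <- rexp(10)
  r1 <- paired_compare(aexp, aexp + 3)
  expect_equal(r1$point_estimate, 3, tolerance = 1e-9)

  # normal differences route to the paired t-test
  set.seed(21)
  x <- rnorm(30); y <- x + rnorm(30, 0.5, 0.3)
  r2 <- paired_compare(x, y)
  expect_equal(r2$method, "paired_t")
  expect_equal(r2$point_estimate, mean(y - x), tolerance = 1e-9)
  expect_true(r2$ci_low <= r2$point_estimate && r2$point_estimate <= r2$ci_high)

  # heavy-tailed differences route to the signed-rank test
  set.seed(22)
  d <- rexp(30)^2
  r3 <- paired_compare(rep(0, 30), d)
  expect_equal(r3$method, "wilcoxon_signed_rank")

  expect_error(paired_compare(1:2, 2:3), "at least 3")
})

test_that("ARE-based signed-rank power reproduces the planning quantities", {
  # dz = 0.86, n = 21, alpha 0.05 two-tailed, normal-parent ARE
  pw <- wilcoxon_power(dz = 0.86, n_pairs = 21)
  expect_equal(round(pw$t_crit, 2), 2.09)
  expect_gte(pw$power, 0.95)
  expect_equal(pw$effective_n, 3 / pi * 21, tolerance = 1e-12)
  expect_equal(pw$delta, 0.86 * sqrt(3 / pi * 21), tolerance = 1e-12)

  # null effect: power equals alpha
  expect_equal(wilcoxon_power(dz = 0, n_pairs = 21)$power, 0.05,
               tolerance = 1e-6)

  # arithmetic identity: are = 1, dz = 1, n = 16 -> delta = 4
  expect_equal(wilcoxon_power(dz = 1, n_pairs = 16, are = 1)$delta, 4)

  # are = 1 equals the plain paired-t power
  pt_power <- power.t.test(n = 20, delta = 0.6, sd = 1, sig.level = 0.05,
                           type = "one.sample")$power
  expect_equal(wilcoxon_power(dz = 0.6, n_pairs = 20, are = 1)$power,
               pt_power, tolerance = 1e-4)

  # strictly increasing in n and |dz|
  p_n <- vapply(10:30, function(n) wilcoxon_power(0.5, n)$power, numeric(1))
  expect_true(all(diff(p_n) > 0))
  p_d <- vapply(seq(0.2, 1.2, by = 0.1),
                function(dz) wilcoxon_power(dz, 15)$power, numeric(1))
  expect_true(all(diff(p_d) > 0))
})

test_that("required_pairs finds the minimal n and matches a naive scan", {
  expect_equal(required_pairs(0.86, 0.05, 0.95), 21L)
  # minimality
  expect_lt(wilcoxon_power(0.86, 20)$power, 0.95)
  # lower target needs fewer pairs
  expect_lt(required_pairs(0.86, 0.05, 0.80), 21L)
  # naive-scan oracle on random specs
  set.seed(30)
  for (i in 1:20) {
    dz <- runif(1, 0.4, 1.2)
    tgt <- runif(1, 0.7, 0.95)
    n <- required_pairs(dz, 0.05, tgt)
    scan <- 2
    while (wilcoxon_power(dz, scan)$power < tgt) scan <- scan + 1
    expect_equal(n, scan)
    expect_gte(wilcoxon_power(dz, n)$power, tgt)
    if (n > 2) expect_lt(wilcoxon_power(dz, n - 1)$power, tgt)
  }
})

test_that("analyze_crossover builds the per-outcome paired table", {
  co <- generate_crossover_cohort(12, duration_s = 300, seed = 40,
                                  waveforms = FALSE)
  tr <- cohort_truth_summaries(co)
  tab <- analyze_crossover(tr)
  expect_true(all(c("ai_pct", "major_ai_pct", "minor_ai_pct", "comfort_b",
                    "leak_pct") %in% tab$outcome))
  ai_row <- tab[tab$outcome == "ai_pct", ]
  expect_lt(ai_row$estimate, 0)  # closed-loop reduces AI
  expect_true(ai_row$ci_low <= ai_row$estimate &&
                ai_row$estimate <= ai_row$ci_high)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  # an absent outcome is flagged, not fabricated
  tab2 <- analyze_crossover(tr, outcomes = c("ai_pct", "nonexistent"))
  expect_true(tab2$missing[tab2$outcome == "nonexistent"])
  # identical arms give a zero difference with p = 1
  tr_same <- tr
  tr_same[tr_same$arm == "closed_loop",
          setdiff(names(tr_same), c("patient_id", "arm"))] <-
    tr_same[tr_same$arm == "conventional",
            setdiff(names(tr_same), c("patient_id", "arm"))]
  tab3 <- analyze_crossover(tr_same, outcomes = "ai_pct")
  expect_equal(tab3$estimate, 0)
  expect_equal(tab3$p_value, 1)
})

test_that("paired p-values are uniform under the exchangeable null", {
  # summary-level null cohorts; Kolmogorov-Smirnov on the p-values
  set.seed(50)
  pvals <- vapply(1:120, function(sd) {
    co <- generate_crossover_cohort(12, duration_s = 120, seed = 1000 + sd,
                                    waveforms = FALSE, null_mode = TRUE)
    tr <- cohort_truth_summaries(co)
    paired_compare(tr$ai_pct[tr$arm == "conventional"],
                   tr$ai_pct[tr$arm == "closed_loop"])$p_two_sided
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
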