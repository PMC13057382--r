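# Paired crossover statistics: Shapiro-Wilk normality routing, paired t /
# Wilcoxon signed-rank comparisons, and Hodges-Lehmann median-difference
# confidence intervals.

#' Normality assessment with routing decision
#'
#' Shapiro-Wilk test combined with skewness and excess-kurtosis screens:
#' the parametric route requires the Shapiro-Wilk p-value at or above
#' `sw_alpha` and absolute skewness / excess kurtosis within bounds.
#'
#' @param values Numeric sample (n >= 3, not all identical).
#' @param sw_alpha Shapiro-Wilk significance threshold (default 0.05).
#' @param skew_max Maximum absolute skewness (default 2).
#' @param kurt_max Maximum absolute excess kurtosis (default 7).
#' @return A list of class `normality_assessment`: `sw_p`, `skewness`,
#'   `excess_kurtosis`, `route` (`"parametric"` or `"nonparametric"`).
#' @export
assess_normality <- function(values, sw_alpha = 0.05, skew_max = 2,
                             kurt_max = 7) {
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop("assess_normality: need at least 3 finite values")
  if (stats::sd(values) == 0)
    stop("assess_normality: constant input, normality undefined")
  sw_p <- stats::shapiro.test(values)$p.value
  sk <- e1071::skewness(values, type = 2)
  # the bias-corrected kurtosis needs 4 observations; at n = 3 the screen
  # rests on Shapiro-Wilk and skewness alone
  ku <- if (length(values) >= 4L) e1071::kurtosis(values, type = 2) else NA_real_
  route <- if (sw_p >= sw_alpha && abs(sk) <= skew_max &&
               (is.na(ku) || abs(ku) <= kurt_max))
    "parametric" else "nonparametric"
  structure(list(sw_p = sw_p, skewness = sk, excess_kurtosis = ku,
                 route = route), class = "normality_assessment")
}

#' Hodges-Lehmann estimate and confidence interval for paired differences
#'
#' The Hodges-Lehmann location estimate is the median of the
#' `n (n + 1) / 2` Walsh averages `(d_i + d_j) / 2`, `i <= j`. Confidence
#' endpoints are Walsh-average order statistics at ranks taken from the
#' exact signed-rank null distribution for `n <= 50` and from its normal
#' approximation above.
#'
#' @param differences Numeric vector of paired differences (n >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `estimate`, `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' hodges_lehmann_ci(c(1, 2, 3))$estimate  # 2
#' @export
hodges_lehmann_ci <- function(differences, conf_level = 0.95) {
  d <- differences[is.finite(differences)]
  n <- length(d)
  if (n < 2L) stop("hodges_lehmann_ci: need at least 2 differences")
  walsh <- sort(outer(d, d, "+")[upper.tri(diag(n), diag = TRUE)] / 2)
  m <- length(walsh)  # n (n + 1) / 2
  alpha <- 1 - conf_level
  if (n <= 50L) {
    qu <- stats::qsignrank(alpha / 2, n)
  } else {
    mu <- m / 2
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    qu <- floor(mu + stats::qnorm(alpha / 2) * sigma)
  }
  if (qu < 1) qu <- 1
  ql <- m - qu
  list(estimate = stats::median(walsh),
       ci_low = walsh[qu],
       ci_high = walsh[min(ql + 1L, m)],
       conf_level = conf_level)
}

#' Paired two-arm comparison with normality routing
#'
#' Computes differences `d = b - a`, routes via [assess_normality()], and
#' applies the paired t-test (mean difference, t-based interval) on the
#' parametric route or the Wilcoxon signed-rank test (Hodges-Lehmann median
#' difference and interval) on the nonparametric route. Zero differences
#' are dropped from the signed-rank statistic (signed-rank convention); the
#' exact null distribution is used when `n <= 25` with no ties or zeros,
#' the normal approximation with continuity correction otherwise.
#'
#' @param a,b Paired numeric vectors (arm A, arm B); incomplete pairs are
#'   dropped.
#' @param conf_level Confidence level (default 0.95).
#' @param outcome Optional outcome label carried into the result.
#' @return A list of class `paired_test_result`: `method`, `statistic`,
#'   `p_two_sided`, `point_estimate`, `ci_low`, `ci_high`, `conf_level`,
#'   `n`, `normality`, `degenerate`, `outcome`.
#' @export
paired_compare <- function(a, b, conf_level = 0.95, outcome = NULL) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("paired_compare: need at least 3 complete pairs")
  d <- b - a
  if (all(d == 0)) {
    return(structure(list(method = "wilcoxon_signed_rank", statistic = NA_real_,
                          p_two_sided = 1, point_estimate = 0,
                          ci_low = 0, ci_high = 0, conf_level = conf_level,
                          n = n, normality = NULL, degenerate = TRUE,
                          outcome = outcome),
                     class = "paired_test_result"))
  }
  norm <- if (stats::sd(d) > 0) assess_normality(d) else
    structure(list(sw_p = 0, skewness = 0, excess_kurtosis = 0,
                   route = "nonparametric"), class = "normality_assessment")
  if (norm$route == "parametric") {
    tt <- stats::t.test(d, conf.level = conf_level)
    res <- list(method = "paired_t", statistic = unname(tt$statistic),
                p_two_sided = tt$p.value,
                point_estimate = unname(tt$estimate),
                ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L])
  } else {
    dz <- d[d != 0]
    exact <- length(dz) <= 25L && !anyDuplicated(abs(dz))
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = exact, correct = TRUE)
    )
    hl <- hodges_lehmann_ci(d, conf_level)
    res <- list(method = "wilcoxon_signed_rank",
                statistic = unname(wt$statistic),
                p_two_sided = wt$p.value,
                point_estimate = hl$estimate,
                ci_low = hl$ci_low, ci_high = hl$ci_high)
  }
  structure(c(res, list(conf_level = conf_level, n = n, normality = norm,
                        degenerate = FALSE, outcome = outcome)),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result>%s %s, n = %d\n",
              if (!is.null(x$outcome)) paste0(" ", x$outcome) else "",
              x$method, x$n))
  cat(sprintf("  estimate %.4g (%.0f%% CI %.4g to %.4g), p = %.4g\n",
              x$point_estimate, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$p_two_sided))
  invisible(x)
}

#' Crossover analysis table
#'
#' Builds the per-outcome comparison table of a two-arm paired crossover:
#' per-arm summaries (median and IQR on the nonparametric route, mean and SD
#' on the parametric route), the paired difference estimate (closed-loop
#' minus conventional) with its confidence interval, and the p-value.
#'
#' @param summaries Data frame with one row per patient and arm, containing
#'   `patient_id`, `arm` (values `"conventional"` / `"closed_loop"`) and the
#'   outcome columns.
#' @param outcomes Character vector of outcome column names to analyze
#'   (default: the AI family, event subtypes, Comfort-B, EtCO2, SpO2, leak
#'   where present).
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame with one row per outcome: `outcome`, `n_pairs`,
#'   formatted `closed_loop` and `conventional` summary strings, numeric
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `method`, `missing`.
#' @export
analyze_crossover <- function(summaries,
                              outcomes = NULL,
                              conf_level = 0.95) {
  stopifnot(all(c("patient_id", "arm") %in% names(summaries)))
  default_outcomes <- c("ai_pct", "major_ai_pct", "minor_ai_pct", "db_pct",
                        "at_pct", "ie_pct", "td_pct", "ec_pct", "lc_pct",
                        "comfort_b", "etco2_mmhg", "spo2_pct", "leak_pct")
  if (is.null(outcomes))
    outcomes <- intersect(default_outcomes, names(summaries))
  conv <- summaries[summaries$arm == "conventional", , drop = FALSE]
  cl <- summaries[summaries$arm == "closed_loop", , drop = FALSE]
  ids <- intersect(conv$patient_id, cl$patient_id)
  if (length(ids) < 3L)
    stop("analyze_crossover: need at least 3 complete patient pairs")
  conv <- conv[match(ids, conv$patient_id), , drop = FALSE]
  cl <- cl[match(ids, cl$patient_id), , drop = FALSE]
  fmt <- function(x, method) {
    if (method == "paired_t") {
      sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
    } else {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
      sprintf("%.1f (%.1f to %.1f)", q[2L], q[1L], q[3L])
    }
  }
  rows <- lapply(outcomes, function(oc) {
    if (!oc %in% names(summaries)) {
      return(data.frame(outcome = oc, n_pairs = NA_integer_,
                        closed_loop = NA_character_,
                        conventional = NA_character_, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, method = NA_character_,
                        missing = TRUE, stringsAsFactors = FALSE))
    }
    av <- conv[[oc]]; bv <- cl[[oc]]
    ok <- is.finite(av) & is.finite(bv)
    if (sum(ok) < 3L || all(av[ok] == bv[ok]) && stats::sd(c(av[ok], bv[ok])) == 0) {
      est <- if (sum(ok) >= 1L) stats::median(bv[ok] - av[ok]) else NA_real_
      return(data.frame(outcome = oc, n_pairs = sum(ok),
                        closed_loop = NA_character_,
                        conventional = NA_character_, estimate = est,
                        ci_low = est, ci_high = est, p_value = 1,
                        method = "degenerate", missing = sum(ok) < 3L,
                        stringsAsFactors = FALSE))
    }
    pc <- paired_compare(av[ok], bv[ok], conf_level, outcome = oc)
    data.frame(outcome = oc, n_pairs = pc$n,
               closed_loop = fmt(bv[ok], pc$method),
               conventional = fmt(av[ok], pc$method),
               estimate = pc$point_estimate, ci_low = pc$ci_low,
               ci_high = pc$ci_high, p_value = pc$p_two_sided,
               method = pc$method, missing = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
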