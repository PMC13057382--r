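# Wilcoxon signed-rank power via the asymptotic-relative-efficiency (ARE)
# method: paired-t noncentral-t machinery applied to an efficiency-deflated
# sample size. With a normal parent distribution the ARE of the signed-rank
# test relative to the paired t-test is 3/pi (about 0.955).

#' Normal-parent asymptotic relative efficiency of the signed-rank test
#' @return `3 / pi` (about 0.9549).
#' @export
are_normal <- function() 3 / pi

#' Power of the Wilcoxon signed-rank test (ARE method)
#'
#' Computes the power of a two-tailed one-sample/paired signed-rank test for
#' a standardized paired effect size (Cohen's dz) by the ARE method: the
#' effective sample size is `are * n_pairs`, the degrees of freedom
#' `effective n - 1` (continuous, non-integer), the noncentrality
#' `dz * sqrt(effective n)`, and the power is the two-sided tail mass of the
#' noncentral t beyond the central-t critical value.
#'
#' @param dz Cohen's dz on the paired differences (mean / SD).
#' @param n_pairs Number of analyzable pairs (>= 2 effective).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param are Asymptotic relative efficiency deflation factor; default the
#'   normal-parent value `3 / pi`. With `are = 1` the result is the plain
#'   paired-t power.
#' @return An object of class `power_result`: `effective_n`, `df`, `delta`
#'   (noncentrality), `t_crit`, `power`, plus the inputs.
#' @examples
#' wilcoxon_power(dz = 0.86, n_pairs = 21)
#' @export
wilcoxon_power <- function(dz, n_pairs, alpha = 0.05, are = are_normal()) {
  stopifnot(is.finite(dz), alpha > 0, alpha < 1, are > 0, are <= 1.5,
            n_pairs >= 2)
  effective_n <- are * n_pairs
  df <- effective_n - 1
  if (df <= 0) stop("wilcoxon_power: non-positive degrees of freedom")
  delta <- dz * sqrt(effective_n)
  t_crit <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(-t_crit, df, ncp = delta) +
    1 - stats::pt(t_crit, df, ncp = delta)
  structure(list(dz = dz, n_pairs = n_pairs, alpha = alpha, are = are,
                 effective_n = effective_n, df = df, delta = delta,
                 t_crit = t_crit, power = power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result> Wilcoxon signed-rank (ARE method)\n")
  cat(sprintf("  dz = %g, n = %d pairs, alpha = %g (two-tailed), ARE = %.4f\n",
              x$dz, x$n_pairs, x$alpha, x$are))
  cat(sprintf("  effective n = %.4f, df = %.4f, delta = %.4f\n",
              x$effective_n, x$df, x$delta))
  cat(sprintf("  critical t = %.4f, power = %.4f\n", x$t_crit, x$power))
  invisible(x)
}

#' Required number of analyzable pairs
#'
#' Smallest `n` such that [wilcoxon_power()] reaches `target_power`.
#'
#' @param dz Cohen's dz (non-zero).
#' @param alpha Two-tailed significance level.
#' @param target_power Target power in `(alpha, 1)`.
#' @param are ARE deflation factor (default normal-parent `3 / pi`).
#' @param n_max Search bound (default `1e6`).
#' @return Integer number of pairs.
#' @examples
#' required_pairs(dz = 0.86, alpha = 0.05, target_power = 0.95)  # 21
#' @export
required_pairs <- function(dz, alpha = 0.05, target_power = 0.95,
                           are = are_normal(), n_max = 1e6) {
  stopifnot(dz != 0, target_power > alpha, target_power < 1)
  n <- max(2, ceiling(2 / are + 1e-9))
  while (n <= n_max) {
    if (wilcoxon_power(dz, n, alpha, are)$power >= target_power)
      return(as.integer(n))
    n <- n + 1
  }
  stop("required_pairs: no n <= n_max reaches the target power")
}
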