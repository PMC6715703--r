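#' Cliff's delta with consistent variance and asymmetric CI
#'
#' Cliff's dominance statistic `delta = P(X > Y) - P(X < Y)`, estimated
#' as the mean of the dominance matrix `d_ij = sign(x_i - y_j)` (ties
#' contribute 0). The standard error is Cliff's (1993) consistent
#' estimator built from the row means, column means, and the full
#' dominance matrix; the confidence interval uses Cliff's bounded
#' asymmetric transformation, which respects the \[-1, 1\] range of the
#' statistic.
#'
#' @param x,y numeric samples from the two groups (each length >= 2).
#' @param conf confidence level for the interval (default 0.95; 0.90
#'   gives the 1-2alpha interval conventional alongside a TOST at
#'   alpha = 0.05).
#' @return object of class `cliffs_delta`: `delta`, `row_means`,
#'   `col_means`, `se`, `ci_low`, `ci_high`, `z`, `p_two_sided`, `n1`,
#'   `n2`, `conf`.
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))$delta # -5/9
#' @export
cliffs_delta <- function(x, y, conf = 0.95) {
  x <- check_numeric_vec(x, "x", 2L)
  y <- check_numeric_vec(y, "y", 2L)
  core <- delta_core(x, y)
  n1 <- core$n1; n2 <- core$n2
  s <- sqrt(core$s2)
  zcrit <- qnorm(1 - (1 - conf) / 2)
  ci <- delta_ci_bounds(core$d_eff, core$s2, zcrit)
  z <- core$d_eff / s
  structure(list(delta = core$delta, row_means = core$row_means,
                 col_means = core$col_means, se = s,
                 ci_low = ci[1], ci_high = ci[2], z = z,
                 p_two_sided = 2 * pnorm(-abs(z)),
                 n1 = n1, n2 = n2, conf = conf),
            class = "cliffs_delta")
}

# Dominance matrix summaries plus Cliff's consistent variance estimate.
# When the estimate is degenerate (|delta| = 1, variance 0) the minimum
# positive substitute (1 - delta^2 + 1/(n1 n2)) / (n1 n2) is used and
# delta is nudged to sign(delta) * (n1 n2 - 1)/(n1 n2) for inference,
# following Cliff's recommendation for boundary samples.
delta_core <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  d <- sign(outer(x, y, "-"))
  delta <- mean(d)
  di <- rowMeans(d); dj <- colMeans(d)
  ss <- sum((d - delta)^2)
  s2 <- (n2^2 * sum((di - delta)^2) + n1^2 * sum((dj - delta)^2) - ss) /
    (n1 * n2 * (n1 - 1) * (n2 - 1))
  d_eff <- delta
  if (1 - delta^2 < 1 / (n1 * n2))
    d_eff <- sign(delta) * (n1 * n2 - 1) / (n1 * n2)
  if (s2 <= 0)
    s2 <- (1 - d_eff^2 + 1 / (n1 * n2)) / (n1 * n2)
  list(delta = delta, d_eff = d_eff, s2 = s2, row_means = di,
       col_means = dj, n1 = n1, n2 = n2)
}

# Cliff's asymmetric CI bounds at normal quantile z.
delta_ci_bounds <- function(d, s2, z) {
  den <- 1 - d^2 + z^2 * s2
  hw <- z * sqrt(s2) * sqrt((1 - d^2)^2 + z^2 * s2)
  lo <- (d - d^3 - hw) / den
  hi <- (d - d^3 + hw) / den
  c(max(-1, lo), min(1, hi))
}

# One-sided p-value for H0: delta >= bound, by closed-form inversion of
# the asymmetric CI: the p-value is 1 - Phi(z*) where z* solves
# upper_ci(z*) = bound. Mirrored for H0: delta <= -bound via d -> -d.
delta_onesided_p_upper <- function(d, s2, bound) {
  c2 <- 1 - d^2
  m <- bound - d
  aa <- 1 - bound^2
  bb <- c2^2 - 2 * c2 * m * bound
  cc <- -c2^2 * m^2
  q2 <- (-bb + sqrt(bb^2 - 4 * aa * cc)) / (2 * aa)
  zstar <- sign(m) * sqrt(max(q2, 0) / s2)
  1 - pnorm(zstar)
}

#' TOST equivalence test for Cliff's delta
#'
#' Two one-sided tests of `H01: delta >= +bound` and
#' `H02: delta <= -bound`. Each one-sided p-value is obtained by
#' inverting Cliff's bounded asymmetric confidence bound (the same
#' transform used for the CI), so the test respects the \[-1, 1\] range
#' of the statistic; `p_equiv` is the larger of the two. Equivalence at
#' level `alpha` is declared when `p_equiv < alpha`, which is identical
#' to the 1-2alpha asymmetric CI lying inside `(-bound, bound)`.
#'
#' @param x,y numeric samples (each length >= 2).
#' @param bound smallest effect size of interest, in (0, 1); default
#'   0.33, the conventional boundary of a "medium" dominance effect.
#' @param alpha one-sided test level (default 0.05).
#' @return object of class `equivalence_result`: `bound`, `alpha`,
#'   `p_lower`, `p_upper`, `p_equiv`, `equivalent`, `delta`, `se`.
#' @export
delta_tost <- function(x, y, bound = 0.33, alpha = 0.05) {
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0 || bound >= 1)
    stop_param("bound", "must be a single number strictly inside (0, 1)")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_param("alpha", "must lie strictly inside (0, 1)")
  x <- check_numeric_vec(x, "x", 2L)
  y <- check_numeric_vec(y, "y", 2L)
  core <- delta_core(x, y)
  p_upper <- delta_onesided_p_upper(core$d_eff, core$s2, bound)
  p_lower <- delta_onesided_p_upper(-core$d_eff, core$s2, bound)
  p_equiv <- max(p_lower, p_upper)
  structure(list(bound = bound, alpha = alpha, p_lower = p_lower,
                 p_upper = p_upper, p_equiv = p_equiv,
                 equivalent = p_equiv < alpha,
                 delta = core$delta, se = sqrt(core$s2)),
            class = "equivalence_result")
}

#' Monte-Carlo power of the delta equivalence test
#'
#' Simulates `B` replicates of two homoskedastic normal samples whose
#' mean shift corresponds to the population dominance effect
#' `true_delta` (shift `sqrt(2) * qnorm((delta + 1)/2) * sigma`), runs
#' the full [delta_tost()] procedure (re-estimating the variance within
#' each replicate) and reports the fraction of replicates declaring
#' equivalence.
#'
#' @param n1,n2 group sample sizes.
#' @param true_delta population Cliff's delta, |delta| < 1.
#' @param bound equivalence bound (default 0.33).
#' @param alpha test level (default 0.05).
#' @param B number of replicates (>= 100; default 10000).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return object of class `power_result`: `power`, `B`, `mc_se`, and
#'   the echoed configuration.
#' @export
mc_power_delta <- function(n1, n2, true_delta = 0, bound = 0.33,
                           alpha = 0.05, B = 10000L, seed = NULL) {
  n1 <- check_count(n1, "n1", 2L)
  n2 <- check_count(n2, "n2", 2L)
  B <- check_count(B, "B", 100L)
  if (!is.numeric(true_delta) || abs(true_delta) >= 1)
    stop_param("true_delta", "must lie strictly inside (-1, 1)")
  shift <- delta_to_shift(true_delta)
  hits <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      core <- delta_core(rnorm(n1) + shift, rnorm(n2))
      p <- max(delta_onesided_p_upper(core$d_eff, core$s2, bound),
               delta_onesided_p_upper(-core$d_eff, core$s2, bound))
      p < alpha
    }, logical(1))
  })
  power <- mean(hits)
  structure(list(power = power, B = B,
                 mc_se = sqrt(power * (1 - power) / B),
                 n1 = n1, n2 = n2, true_effect = true_delta,
                 bound = bound, alpha = alpha, seed = seed,
                 kind = "cliffs_delta_tost"),
            class = "power_result")
}

#' Pearson chi-square for a 2x2 table, without continuity correction
#'
#' Closed form `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with one
#' degree of freedom, plus the phi coefficient `sqrt(chi2 / N)`.
#'
#' @param a,b,c,d cell counts, row-wise (`a`,`b` first row).
#' @return object of class `contingency_result`: `chi2`, `df`, `p`,
#'   `phi`, `n`.
#' @examples
#' chi_square_2x2(62, 21, 40, 19)
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  for (nm in names(counts))
    if (!is.numeric(counts[[nm]]) || counts[[nm]] < 0 ||
        counts[[nm]] != round(counts[[nm]]))
      stop_param(nm, "must be a non-negative integer count")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (n <= 0 || any(margins == 0))
    stop("2x2 table has a zero margin; chi-square undefined", call. = FALSE)
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  structure(list(chi2 = chi2, df = 1L,
                 p = pchisq(chi2, 1, lower.tail = FALSE),
                 phi = sqrt(chi2 / n), n = n),
            class = "contingency_result")
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value obtained by summing the hypergeometric
#' probabilities of all tables (with the observed margins) no more
#' probable than the observed one.
#'
#' @param a,b,c,d cell counts, row-wise.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(2, 0, 0, 2) # 1/3
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  for (nm in names(counts))
    if (!is.numeric(counts[[nm]]) || counts[[nm]] < 0 ||
        counts[[nm]] != round(counts[[nm]]))
      stop_param(nm, "must be a non-negative integer count")
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  if (m1 + m2 == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' @export
print.cliffs_delta <- function(x, ...) {
  cat(sprintf(
    "Cliff's delta = %.3f, %d%% CI [%.3f, %.3f], z = %.3f, p = %.4f\n",
    x$delta, round(100 * x$conf), x$ci_low, x$ci_high, x$z, x$p_two_sided))
  invisible(x)
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "TOST (|bound| = %.2f): p_equiv = %.4f (%sequivalent at alpha = %.2f)\n",
    x$bound, x$p_equiv, if (x$equivalent) "" else "not ", x$alpha))
  invisible(x)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo power = %.3f (B = %d, MC SE = %.4f)\n",
              x$power, x$B, x$mc_se))
  invisible(x)
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.2f, p = %.3f, phi = %.3f (N = %d)\n",
              x$df, x$chi2, x$p, x$phi, x$n))
  invisible(x)
}
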