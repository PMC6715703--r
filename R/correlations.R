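#' Spearman rank correlation
#'
#' Product-moment correlation of midranks (average ranks for ties).
#'
#' @param x,y paired numeric vectors, length >= 3, all finite.
#' @return the rank correlation coefficient in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  x <- check_numeric_vec(x, "x", 3L)
  y <- check_numeric_vec(y, "y", 3L)
  if (length(x) != length(y))
    stop("`x` and `y` must be paired (equal length)", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  cor(rank(x), rank(y))
}

# Standard error of atanh(r_s). "caruso_cliff" uses the rank-correlation
# family form sqrt((1 + r^2/2)/(n - 3)); "fixed" uses sqrt(1.06/(n - 3)).
spearman_se <- function(r_s, n, se_method = c("caruso_cliff", "fixed")) {
  se_method <- match.arg(se_method)
  if (se_method == "caruso_cliff") sqrt((1 + r_s^2 / 2) / (n - 3))
  else sqrt(1.06 / (n - 3))
}

#' Z-test for a Spearman correlation
#'
#' Tests `H0: rho_s = 0` with `z = atanh(r_s) / se` on the Fisher-z
#' scale, using a rank-correlation standard error (default
#' `sqrt((1 + r_s^2/2)/(n - 3))`).
#'
#' @param r_s observed Spearman coefficient.
#' @param n number of pairs (>= 4).
#' @param se_method `"caruso_cliff"` (default) or `"fixed"`
#'   (`sqrt(1.06/(n-3))`).
#' @return object of class `spearman_test`: `r_s`, `n`, `z`, `se`,
#'   `p_two_sided`, `boundary` (TRUE when |r_s| = 1).
#' @export
spearman_test <- function(r_s, n, se_method = "caruso_cliff") {
  if (!is.numeric(r_s) || length(r_s) != 1L || abs(r_s) > 1)
    stop_param("r_s", "must be a single value in [-1, 1]")
  n <- check_count(n, "n", 4L)
  if (abs(r_s) == 1) {
    return(structure(list(r_s = r_s, n = n, z = sign(r_s) * Inf,
                          se = spearman_se(r_s, n, se_method),
                          p_two_sided = 0, boundary = TRUE),
                     class = "spearman_test"))
  }
  se <- spearman_se(r_s, n, se_method)
  z <- atanh(r_s) / se
  structure(list(r_s = r_s, n = n, z = z, se = se,
                 p_two_sided = 2 * pnorm(-abs(z)), boundary = FALSE),
            class = "spearman_test")
}

#' TOST equivalence test for a Spearman correlation
#'
#' Two one-sided z-tests on the Fisher-z (atanh) scale against
#' `+/- atanh(bound)`; `p_equiv` is the larger one-sided p-value.
#'
#' @param r_s observed Spearman coefficient.
#' @param n number of pairs (>= 4).
#' @param bound equivalence bound on the correlation scale, in (0, 1);
#'   default 0.30 (conventional "medium" correlation).
#' @param alpha test level (default 0.05).
#' @param se_method see [spearman_test()].
#' @return object of class `equivalence_result` with fields `bound`,
#'   `alpha`, `p_lower`, `p_upper`, `p_equiv`, `equivalent`, `r_s`, `se`.
#' @export
corr_tost <- function(r_s, n, bound = 0.30, alpha = 0.05,
                      se_method = "caruso_cliff") {
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0 || bound >= 1)
    stop_param("bound", "must be a single number strictly inside (0, 1)")
  if (!is.numeric(r_s) || length(r_s) != 1L || abs(r_s) > 1)
    stop_param("r_s", "must be a single value in [-1, 1]")
  n <- check_count(n, "n", 4L)
  se <- spearman_se(r_s, n, se_method)
  zb <- atanh(bound)
  zr <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r_s)))
  p_upper <- pnorm((zr - zb) / se)
  p_lower <- 1 - pnorm((zr + zb) / se)
  p_equiv <- max(p_lower, p_upper)
  structure(list(bound = bound, alpha = alpha, p_lower = p_lower,
                 p_upper = p_upper, p_equiv = p_equiv,
                 equivalent = p_equiv < alpha, r_s = r_s, se = se),
            class = "equivalence_result")
}

#' Monte-Carlo power of the correlation equivalence test
#'
#' Simulates `B` bivariate-normal samples with population (Pearson)
#' correlation `true_rho`, computes the sample Spearman coefficient of
#' each, and reports the fraction of replicates in which [corr_tost()]
#' declares equivalence.
#'
#' @param n number of pairs per replicate (>= 5).
#' @param true_rho population correlation, |rho| < 1.
#' @param bound equivalence bound (default 0.30).
#' @param alpha test level (default 0.05).
#' @param B replicates (>= 100; default 10000).
#' @param seed optional integer seed; RNG state restored afterwards.
#' @param se_method see [spearman_test()].
#' @return object of class `power_result`.
#' @export
mc_power_corr <- function(n, true_rho = 0, bound = 0.30, alpha = 0.05,
                          B = 10000L, seed = NULL,
                          se_method = "caruso_cliff") {
  n <- check_count(n, "n", 5L)
  B <- check_count(B, "B", 100L)
  if (!is.numeric(true_rho) || abs(true_rho) >= 1)
    stop_param("true_rho", "must lie strictly inside (-1, 1)")
  zb <- atanh(bound)
  hits <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      x <- rnorm(n)
      y <- true_rho * x + sqrt(1 - true_rho^2) * rnorm(n)
      r <- cor(rank(x), rank(y))
      se <- spearman_se(r, n, se_method)
      zr <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r)))
      max(pnorm((zr - zb) / se), 1 - pnorm((zr + zb) / se)) < alpha
    }, logical(1))
  })
  power <- mean(hits)
  structure(list(power = power, B = B,
                 mc_se = sqrt(power * (1 - power) / B),
                 n1 = n, n2 = NA_integer_, true_effect = true_rho,
                 bound = bound, alpha = alpha, seed = seed,
                 kind = "spearman_tost"),
            class = "power_result")
}

fisher_ci <- function(r, n, conf) {
  zc <- qnorm(1 - (1 - conf) / 2)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  tanh(c(z - zc * se, z + zc * se))
}

#' Zou's CI for the difference of two independent correlations
#'
#' Back-transforms per-correlation Fisher-z confidence limits
#' `(l_k, u_k)` and combines them:
#' `L = r1 - r2 - sqrt((r1 - l1)^2 + (u2 - r2)^2)`,
#' `U = r1 - r2 + sqrt((u1 - r1)^2 + (r2 - l2)^2)`.
#'
#' @param r1,r2 sample correlations, |r| < 1.
#' @param n1,n2 sample sizes (>= 4).
#' @param conf confidence level (default 0.95).
#' @return object of class `corr_diff`: `diff`, `ci_low`, `ci_high`,
#'   `kind`, and the echoed inputs.
#' @export
zou_diff_independent <- function(r1, n1, r2, n2, conf = 0.95) {
  for (r in c(r1 = r1, r2 = r2))
    if (!is.numeric(r) || abs(r) >= 1)
      stop_param("r", "correlations must lie strictly inside (-1, 1)")
  n1 <- check_count(n1, "n1", 4L)
  n2 <- check_count(n2, "n2", 4L)
  ci1 <- fisher_ci(r1, n1, conf)
  ci2 <- fisher_ci(r2, n2, conf)
  d <- r1 - r2
  lo <- d - sqrt((r1 - ci1[1])^2 + (ci2[2] - r2)^2)
  hi <- d + sqrt((ci1[2] - r1)^2 + (r2 - ci2[1])^2)
  structure(list(diff = d, ci_low = lo, ci_high = hi,
                 kind = "independent", conf = conf,
                 inputs = list(r1 = r1, n1 = n1, r2 = r2, n2 = n2)),
            class = "corr_diff")
}

#' Zou's CI for the difference of two dependent, overlapping correlations
#'
#' For correlations `r_jk` and `r_jh` sharing variable `j` and measured
#' on the same `n` subjects, combines back-transformed Fisher-z limits
#' with the estimated correlation `c` between the two correlation
#' estimates (the Pearson-Filon covariance term for overlapping
#' correlations):
#' `L = r_jk - r_jh - sqrt((r_jk - l1)^2 + (u2 - r_jh)^2 - 2 c (r_jk - l1)(u2 - r_jh))`
#' and the mirrored upper limit.
#'
#' @param r_jk,r_jh,r_kh the three sample correlations among variables
#'   j, k, h; the implied 3x3 correlation matrix must be positive
#'   semidefinite.
#' @param n number of subjects (>= 4).
#' @param conf confidence level (default 0.95).
#' @return object of class `corr_diff` (`kind = "dependent_overlapping"`).
#' @export
zou_diff_dependent <- function(r_jk, r_jh, r_kh, n, conf = 0.95) {
  rs <- c(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh)
  for (nm in names(rs))
    if (!is.numeric(rs[[nm]]) || abs(rs[[nm]]) >= 1)
      stop_param(nm, "must lie strictly inside (-1, 1)")
  n <- check_count(n, "n", 4L)
  R <- matrix(c(1, r_jk, r_jh,
                r_jk, 1, r_kh,
                r_jh, r_kh, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlation triple is not positive semidefinite", call. = FALSE)
  # correlation between the two correlation estimates (overlapping case)
  cterm <- ((r_kh * (1 - r_jk^2 - r_jh^2)) -
              0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)) /
    ((1 - r_jk^2) * (1 - r_jh^2))
  ci1 <- fisher_ci(r_jk, n, conf)
  ci2 <- fisher_ci(r_jh, n, conf)
  d <- r_jk - r_jh
  lo <- d - sqrt((r_jk - ci1[1])^2 + (ci2[2] - r_jh)^2 -
                   2 * cterm * (r_jk - ci1[1]) * (ci2[2] - r_jh))
  hi <- d + sqrt((ci1[2] - r_jk)^2 + (r_jh - ci2[1])^2 -
                   2 * cterm * (ci1[2] - r_jk) * (r_jh - ci2[1]))
  structure(list(diff = d, ci_low = lo, ci_high = hi,
                 kind = "dependent_overlapping", conf = conf,
                 cor_between_estimates = cterm,
                 inputs = list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh,
                               n = n)),
            class = "corr_diff")
}

#' @export
print.spearman_test <- function(x, ...) {
  cat(sprintf("Spearman r_s = %.3f (n = %d): z = %.3f, p = %.4f\n",
              x$r_s, x$n, x$z, x$p_two_sided))
  invisible(x)
}

#' @export
print.corr_diff <- function(x, ...) {
  cat(sprintf("Correlation difference (%s) = %.3f, %d%% CI [%.3f, %.3f]\n",
              x$kind, x$diff, round(100 * x$conf), x$ci_low, x$ci_high))
  invisible(x)
}
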