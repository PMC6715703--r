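#' Harrell-Davis quantile estimator
#'
#' Estimates the `q`-th quantile of a sample as a weighted average of all
#' order statistics, with weights given by increments of a
#' Beta((n+1)q, (n+1)(1-q)) distribution function. The estimator is more
#' efficient than the sample quantile for small, skewed samples, which is
#' why it is the default summary for method-of-limits trial sets.
#'
#' @param x numeric vector of observations (all finite, length >= 1).
#' @param q quantile level, strictly between 0 and 1.
#' @return An object of class `hd_estimate`: a list with `estimate`,
#'   `q`, `n`, and the per-order-statistic `weights` (non-negative,
#'   summing to one).
#' @examples
#' hd_quantile(c(1, 2, 3, 10), 0.5)$estimate
#' @export
hd_quantile <- function(x, q = 0.5) {
  x <- check_numeric_vec(x, "x", min_len = 1L)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop_param("q", "must be a single number strictly inside (0, 1)")
  n <- length(x)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  i <- seq_len(n)
  w <- pbeta(i / n, a, b) - pbeta((i - 1) / n, a, b)
  est <- sum(w * sort(x))
  structure(list(estimate = est, q = q, n = n, weights = w),
            class = "hd_estimate")
}

#' Harrell-Davis quantiles as a plain numeric vector
#'
#' Convenience wrapper around [hd_quantile()] for several quantile levels.
#'
#' @param x numeric vector.
#' @param probs quantile levels in (0, 1).
#' @return named numeric vector of estimates.
#' @export
hd_quantiles <- function(x, probs = c(0.25, 0.5, 0.75)) {
  out <- vapply(probs, function(p) hd_quantile(x, p)$estimate, numeric(1))
  names(out) <- format(probs)
  out
}

#' Gini's mean difference
#'
#' Mean absolute difference over all ordered pairs of observations,
#' i.e. `sum_{i != j} |x_i - x_j| / (n (n - 1))`. A robust, highly
#' efficient dispersion measure; applied to a subject's trial set it
#' indexes trial-to-trial (intra-individual) variability. Computed via
#' the O(n log n) order-statistic identity
#' `GMD = 2 / (n (n - 1)) * sum_i (2 i - n - 1) x_(i)`.
#'
#' @param x numeric vector, length >= 2.
#' @return non-negative scalar; zero iff all values are equal.
#' @examples
#' gmd(c(1, 2, 4)) # 2
#' @export
gmd <- function(x) {
  x <- check_numeric_vec(x, "x", min_len = 2L)
  n <- length(x)
  xs <- sort(x)
  2 * sum((2 * seq_len(n) - n - 1) * xs) / (n * (n - 1))
}

#' Change from the 32 degC baseline
#'
#' Converts a recorded thermode temperature to the detection-threshold
#' scale: the (positive) change from the 32 degC starting temperature,
#' upward for warm trials and downward for cool trials.
#'
#' @param temperature numeric vector of recorded temperatures in degC,
#'   each within the device limits \[0, 50\].
#' @param modality `"warm"` or `"cool"` (scalar or vector recycled against
#'   `temperature`).
#' @return numeric vector of changes in degC.
#' @export
threshold_change <- function(temperature, modality) {
  temperature <- check_numeric_vec(temperature, "temperature")
  if (any(temperature < 0 | temperature > 50))
    stop("`temperature` outside the device bounds [0, 50] degC",
         call. = FALSE)
  modality <- match_modality(modality, length(temperature))
  ifelse(modality == "warm", temperature - 32, 32 - temperature)
}

match_modality <- function(modality, n) {
  if (!all(modality %in% c("warm", "cool")))
    stop("`modality` must be \"warm\" or \"cool\"", call. = FALSE)
  rep_len(as.character(modality), n)
}

#' Per-subject threshold summary
#'
#' Summarizes one subject's trials: the Harrell-Davis median and Gini's
#' mean difference of the change-from-baseline values pooled across
#' blocks, plus per-block Harrell-Davis medians (used for block
#' reliability). A modality with no trials yields `NA` fields.
#'
#' @param trials data frame with columns `modality`, `block`,
#'   `temperature` (and optionally `subject_id`) for a single subject.
#' @return one-row data frame with columns `subject_id`,
#'   `warm_threshold`, `cool_threshold`, `warm_gmd`, `cool_gmd`,
#'   `warm_block1`, `warm_block2`, `cool_block1`, `cool_block2`,
#'   `n_warm`, `n_cool`.
#' @export
summarize_subject <- function(trials) {
  stopifnot(is.data.frame(trials))
  need <- c("modality", "block", "temperature")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  id <- if ("subject_id" %in% names(trials) && nrow(trials))
    as.character(trials$subject_id[1]) else NA_character_
  out <- list(subject_id = id)
  for (mod in c("warm", "cool")) {
    rows <- trials[trials$modality == mod, , drop = FALSE]
    n <- nrow(rows)
    thr <- gm <- b1 <- b2 <- NA_real_
    if (n >= 2) {
      ch <- threshold_change(rows$temperature, mod)
      thr <- hd_quantile(ch, 0.5)$estimate
      gm <- gmd(ch)
      for (b in 1:2) {
        cb <- ch[rows$block == b]
        if (length(cb) >= 1)
          assign(paste0("b", b), hd_quantile(cb, 0.5)$estimate)
      }
    } else if (n == 1) {
      thr <- threshold_change(rows$temperature, mod)
    }
    out[[paste0(mod, "_threshold")]] <- thr
    out[[paste0(mod, "_gmd")]] <- gm
    out[[paste0(mod, "_block1")]] <- b1
    out[[paste0(mod, "_block2")]] <- b2
    out[[paste0("n_", mod)]] <- n
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Cohort-level threshold summary table
#'
#' Applies [summarize_subject()] to every subject in a trial table.
#'
#' @param trials trial table (`subject_id`, `modality`, `block`, `trial`,
#'   `temperature`).
#' @return data frame, one row per subject.
#' @export
summarize_thresholds <- function(trials) {
  stopifnot(is.data.frame(trials), "subject_id" %in% names(trials))
  ids <- unique(as.character(trials$subject_id))
  out <- do.call(rbind, lapply(ids, function(id)
    summarize_subject(trials[trials$subject_id == id, , drop = FALSE])))
  rownames(out) <- NULL
  out
}

#' Two-way mixed, consistency, average-measures ICC
#'
#' Shrout-Fleiss ICC(3, k) with k = 2: `(MS_rows - MS_error) / MS_rows`,
#' quantifying the consistency of per-block threshold medians across
#' blocks. The confidence interval is the standard F-based interval.
#' A fixed additive offset between blocks does not reduce this ICC.
#'
#' @param block1,block2 paired numeric vectors (one value per subject),
#'   equal length >= 3.
#' @param conf confidence level for the interval (default 0.95).
#' @return object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `ms_rows`, `ms_error`, `k`, `n`, `degenerate`.
#' @export
icc_consistency_avg <- function(block1, block2, conf = 0.95) {
  block1 <- check_numeric_vec(block1, "block1", 3L)
  block2 <- check_numeric_vec(block2, "block2", 3L)
  if (length(block1) != length(block2))
    stop("`block1` and `block2` must have equal length", call. = FALSE)
  n <- length(block1)
  k <- 2L
  m <- cbind(block1, block2)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  ms_rows <- k * sum((row_means - grand)^2) / (n - 1)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- sum((m - outer(row_means, rep(1, k)) -
                   outer(rep(1, n), col_means) + grand)^2)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  degenerate <- ms_rows <= .Machine$double.eps * max(1, abs(grand))
  if (degenerate) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, ms_rows = ms_rows,
                          ms_error = ms_err, k = k, n = n,
                          degenerate = TRUE), class = "icc_result"))
  }
  icc <- (ms_rows - ms_err) / ms_rows
  ci_low <- ci_high <- icc
  if (ms_err > 0) {
    alpha <- 1 - conf
    f0 <- ms_rows / ms_err
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f0 / qf(1 - alpha / 2, df1, df2)
    fu <- f0 * qf(1 - alpha / 2, df2, df1)
    ci_low <- 1 - 1 / fl
    ci_high <- 1 - 1 / fu
  }
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 ms_rows = ms_rows, ms_error = ms_err, k = k, n = n,
                 degenerate = FALSE), class = "icc_result")
}

#' Boxplot-rule outlier flags
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' computed by the linear-interpolation (type 7) convention.
#'
#' @param x numeric vector, length >= 4.
#' @return logical vector, `TRUE` for flagged values.
#' @export
boxplot_outliers <- function(x) {
  x <- check_numeric_vec(x, "x", 4L)
  qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  x < qs[1] - 1.5 * iqr | x > qs[2] + 1.5 * iqr
}

#' Add within-group outlier flags to a threshold summary
#'
#' Applies the boxplot rule separately within each diagnostic group (the
#' group distributions, not the pooled sample, define the fences).
#'
#' @param summary threshold summary (from [summarize_thresholds()]).
#' @param group vector of group labels, one per summary row.
#' @return `summary` with logical columns `outlier_warm`, `outlier_cool`,
#'   `outlier_warm_gmd`, `outlier_cool_gmd` appended.
#' @export
flag_outliers <- function(summary, group) {
  stopifnot(is.data.frame(summary), length(group) == nrow(summary))
  cols <- c(outlier_warm = "warm_threshold", outlier_cool = "cool_threshold",
            outlier_warm_gmd = "warm_gmd", outlier_cool_gmd = "cool_gmd")
  for (fl in names(cols)) summary[[fl]] <- NA
  for (g in unique(group)) {
    sel <- which(group == g)
    for (fl in names(cols)) {
      v <- summary[[cols[[fl]]]][sel]
      ok <- is.finite(v)
      if (sum(ok) >= 4) {
        flags <- rep(NA, length(v))
        flags[ok] <- boxplot_outliers(v[ok])
        summary[[fl]][sel] <- flags
      }
    }
  }
  summary
}

#' @export
print.hd_estimate <- function(x, ...) {
  cat(sprintf("Harrell-Davis quantile (q = %g, n = %d): %.4f\n",
              x$q, x$n, x$estimate))
  invisible(x)
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("ICC(3,", x$k, "): degenerate (no between-subject variance)\n")
  } else {
    cat(sprintf("ICC(3,%d) = %.3f, 95%% CI [%.3f, %.3f] (n = %d)\n",
                x$k, x$icc, x$ci_low, x$ci_high, x$n))
  }
  invisible(x)
}
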