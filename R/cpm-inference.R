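#' Likelihood-ratio and Wald inference for a CPM fit
#'
#' Compares a fitted CPM against a nested null fit on the same data:
#' the likelihood-ratio chi-square `2 (LL - LL0)` with degrees of
#' freedom equal to the difference in slope count, Nagelkerke's
#' normalized pseudo R-squared
#' `(1 - exp(-LR/n)) / (1 - exp(2 LL0 / n))`, and per-coefficient Wald
#' statistics with adjusted odds ratios `exp(beta)` and 95% CIs.
#'
#' @param fit a `cpm_fit`.
#' @param null_fit a nested `cpm_fit` on the same outcome (defaults to
#'   the intercept-only model implicit in `fit`).
#' @return object of class `model_fit_stats`: `lr_chi2`, `df`, `p`,
#'   `nagelkerke_r2`, and `coef_table` (one row per slope: `beta`,
#'   `se`, `aor`, `aor_low`, `aor_high`, `wald_chi2`, `p`).
#' @export
model_inference <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "cpm_fit"))
  if (is.null(null_fit)) {
    ll0 <- fit$loglik_null
    p0 <- 0L
  } else {
    stopifnot(inherits(null_fit, "cpm_fit"))
    if (null_fit$n != fit$n || null_fit$J != fit$J ||
        !isTRUE(all.equal(null_fit$y_values, fit$y_values)))
      stop("models are not fitted to the same outcome", call. = FALSE)
    if (!all(null_fit$predictors %in% fit$predictors))
      stop("`null_fit` is not nested in `fit`", call. = FALSE)
    ll0 <- null_fit$loglik
    p0 <- length(null_fit$beta)
  }
  n <- fit$n
  lr <- max(0, 2 * (fit$loglik - ll0))
  df <- length(fit$beta) - p0
  p <- if (df > 0) pchisq(lr, df, lower.tail = FALSE) else NA_real_
  denom <- 1 - exp(2 * ll0 / n)
  r2 <- if (denom > 0) (1 - exp(-lr / n)) / denom else NA_real_
  ct <- NULL
  if (length(fit$beta)) {
    z <- fit$beta / fit$se_beta
    ct <- data.frame(
      predictor = names(fit$beta),
      beta = unname(fit$beta),
      se = unname(fit$se_beta),
      aor = exp(unname(fit$beta)),
      aor_low = exp(unname(fit$beta) - qnorm(0.975) * unname(fit$se_beta)),
      aor_high = exp(unname(fit$beta) + qnorm(0.975) * unname(fit$se_beta)),
      wald_chi2 = unname(z)^2,
      p = 2 * pnorm(-abs(unname(z))),
      stringsAsFactors = FALSE)
  }
  structure(list(lr_chi2 = lr, df = df, p = p, nagelkerke_r2 = r2,
                 coef_table = ct, n = n),
            class = "model_fit_stats")
}

#' Best-subset CPM selection by BIC weights
#'
#' Fits a CPM for every subset of the candidate predictors (base
#' predictors always included), scores each with
#' `BIC = -2 LL + k log(n)` where `k` counts intercepts and slopes, and
#' converts BIC differences into Akaike-style weights
#' `w_m = exp(-Delta BIC_m / 2) / sum(...)`. Because the intercept count
#' is identical across subsets of a fixed outcome, Delta BIC depends
#' only on the slope sets. Failed fits are dropped with a warning and
#' the weights renormalized.
#'
#' @param y outcome vector.
#' @param X_base matrix/data frame of predictors forced into every
#'   model (may be `NULL`).
#' @param X_candidates matrix/data frame of candidate predictors
#'   (nonempty).
#' @param ... passed to [fit_cpm()].
#' @return object of class `model_selection`: `table` (one row per
#'   fitted subset: `model`, `k_slopes`, `bic`, `weight`,
#'   `evidence_ratio`), `inclusion_probs`, `best_id`, `best_fit`,
#'   `n_failed`.
#' @export
best_subset_bic <- function(y, X_base = NULL, X_candidates, ...) {
  Xc <- as.matrix(X_candidates)
  if (is.null(colnames(Xc)))
    colnames(Xc) <- paste0("c", seq_len(ncol(Xc)))
  if (ncol(Xc) < 1) stop("`X_candidates` must be nonempty", call. = FALSE)
  Xb <- if (!is.null(X_base)) as.matrix(X_base) else NULL
  if (!is.null(Xb) && is.null(colnames(Xb)))
    colnames(Xb) <- paste0("b", seq_len(ncol(Xb)))
  k <- ncol(Xc)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(subsets) <- colnames(Xc)
  n <- length(y)
  rows <- list()
  fits <- list()
  n_failed <- 0L
  for (m in seq_len(nrow(subsets))) {
    inc <- unlist(subsets[m, , drop = FALSE])
    Xm <- cbind(Xb, Xc[, inc, drop = FALSE])
    if (!is.null(Xm) && ncol(Xm) == 0) Xm <- NULL
    fit <- tryCatch(suppressWarnings(fit_cpm(y, Xm, ...)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      warning("subset model ", m, " failed to fit; excluded",
              call. = FALSE)
      next
    }
    kp <- (fit$J - 1L) + length(fit$beta)
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste(colnames(Xc)[inc], collapse = "+"),
      id = m, k_slopes = length(fit$beta),
      loglik = fit$loglik, bic = -2 * fit$loglik + kp * log(n),
      stringsAsFactors = FALSE)
    fits[[as.character(m)]] <- list(fit = fit, inc = inc)
  }
  if (!length(rows))
    stop("all candidate-subset fits failed", call. = FALSE)
  tab <- do.call(rbind, rows)
  dbic <- tab$bic - min(tab$bic)
  w <- exp(-dbic / 2)
  tab$weight <- w / sum(w)
  tab$evidence_ratio <- max(tab$weight) / tab$weight
  best_row <- which.max(tab$weight)
  incl <- vapply(colnames(Xc), function(v) {
    in_model <- vapply(tab$id, function(id) fits[[as.character(id)]]$inc[[v]],
                       logical(1))
    sum(tab$weight[in_model])
  }, numeric(1))
  structure(list(table = tab[order(tab$bic), , drop = FALSE],
                 inclusion_probs = incl,
                 best_id = tab$id[best_row],
                 best_model = tab$model[best_row],
                 best_fit = fits[[as.character(tab$id[best_row])]]$fit,
                 n_failed = n_failed),
            class = "model_selection")
}

# Drop columns that are constant or collinear with already-kept columns
# (plus the implicit intercept), warning about each.
prune_predictors <- function(data, cols, kept) {
  out <- character(0)
  for (v in cols) {
    test_cols <- c(kept, out, v)
    X <- cbind(1, as.matrix(data[, test_cols, drop = FALSE]))
    if (qr(X)$rank == length(test_cols) + 1L) {
      out <- c(out, v)
    } else {
      warning("predictor `", v,
              "` dropped (constant or collinear)", call. = FALSE)
    }
  }
  out
}

#' Three-step hierarchical CPM fits
#'
#' Step 1 regresses the outcome on the baseline covariates; step 2 adds
#' the best BIC-selected subset of candidate predictors (baseline
#' forced in); step 3 appends the trial-variability (GMD) column to the
#' step-2 model. Between-step likelihood-ratio tests and Nagelkerke
#' R-squared increments quantify what each step adds.
#'
#' @param y outcome vector.
#' @param data data frame holding all predictor columns.
#' @param baseline character vector of baseline covariate columns.
#' @param candidates character vector of candidate predictor columns.
#' @param gmd_col name of the trial-variability column added at step 3.
#' @param ... passed to [fit_cpm()].
#' @return object of class `cpm_hierarchy`: `fits` (list of 3
#'   `cpm_fit`s), `stats` (per-step `model_fit_stats` vs the
#'   intercept-only model), `selection` (`model_selection` from step 2),
#'   `lr_steps` (step-over-step LR tests), `delta_r2`.
#' @export
hierarchical_models <- function(y, data, baseline, candidates, gmd_col,
                                ...) {
  stopifnot(is.data.frame(data))
  need <- c(baseline, candidates, gmd_col)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("`data` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  baseline <- prune_predictors(data, baseline, character(0))
  candidates <- prune_predictors(data, candidates, baseline)
  Xb <- as.matrix(data[, baseline, drop = FALSE])
  fit1 <- fit_cpm(y, Xb, ...)
  sel <- best_subset_bic(y, Xb, data[, candidates, drop = FALSE], ...)
  fit2 <- sel$best_fit
  kept <- setdiff(fit2$predictors, baseline)
  step3_cols <- prune_predictors(data, c(baseline, kept, gmd_col),
                                 character(0))
  X3 <- as.matrix(data[, step3_cols, drop = FALSE])
  fit3 <- fit_cpm(y, X3, ...)
  fits <- list(step1 = fit1, step2 = fit2, step3 = fit3)
  stats <- lapply(fits, model_inference)
  lr_steps <- list(
    step2_vs_step1 = model_inference(fit2, fit1),
    step3_vs_step2 = model_inference(fit3, fit2))
  r2 <- vapply(stats, function(s) s$nagelkerke_r2, numeric(1))
  structure(list(fits = fits, stats = stats, selection = sel,
                 lr_steps = lr_steps,
                 delta_r2 = c(step2 = unname(r2[2] - r2[1]),
                              step3 = unname(r2[3] - r2[2]))),
            class = "cpm_hierarchy")
}

#' @export
print.model_fit_stats <- function(x, ...) {
  cat(sprintf("Model fit: chi2(%d) = %.2f, p = %.4f, Nagelkerke R2 = %.3f\n",
              x$df, x$lr_chi2, x$p, x$nagelkerke_r2))
  if (!is.null(x$coef_table)) {
    ct <- x$coef_table
    ct[-1] <- lapply(ct[-1], round, 3)
    print(ct, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Best-subset BIC selection; best model: {",
      if (nzchar(x$best_model)) x$best_model else "baseline only", "}\n")
  tab <- x$table
  tab[c("loglik", "bic", "weight", "evidence_ratio")] <-
    lapply(tab[c("loglik", "bic", "weight", "evidence_ratio")], round, 3)
  print(utils::head(tab, 8), row.names = FALSE)
  cat("Inclusion probabilities:\n")
  print(round(x$inclusion_probs, 3))
  invisible(x)
}

#' @export
print.cpm_hierarchy <- function(x, ...) {
  for (s in names(x$fits)) {
    cat("==", s, "==\n")
    print(x$stats[[s]])
  }
  cat(sprintf("Delta R2: step2 = %.3f, step3 = %.3f\n",
              x$delta_r2["step2"], x$delta_r2["step3"]))
  invisible(x)
}
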