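#' Analysis configuration
#'
#' Collects the tuning constants of the full pipeline: equivalence
#' bounds (0.33 on the dominance scale, 0.30 on the correlation scale),
#' the test level, the CI level reported alongside group comparisons
#' (0.90, the 1-2alpha interval conventional with a TOST at 0.05), the
#' Monte-Carlo replicate count, the number of imputations, and the
#' adult/child boundary (18.0 years, exclusive).
#'
#' @param delta_bound equivalence bound for Cliff's delta.
#' @param corr_bound equivalence bound for Spearman correlations.
#' @param alpha test level.
#' @param ci_level CI level for reported delta intervals.
#' @param B Monte-Carlo replicates for power analyses.
#' @param M number of multiple imputations.
#' @param adult_age age (years) at or above which a subject is adult.
#' @param seed optional integer root seed.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(delta_bound = 0.33, corr_bound = 0.30,
                            alpha = 0.05, ci_level = 0.90, B = 10000L,
                            M = 20L, adult_age = 18, seed = NULL) {
  for (nm in c("delta_bound", "corr_bound"))
    if (get(nm) <= 0 || get(nm) >= 1)
      stop_param(nm, "must lie strictly inside (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_param("alpha", "must be in (0, 1)")
  if (ci_level <= 0 || ci_level >= 1)
    stop_param("ci_level", "must be in (0, 1)")
  structure(list(delta_bound = delta_bound, corr_bound = corr_bound,
                 alpha = alpha, ci_level = ci_level,
                 B = check_count(B, "B", 100L),
                 M = check_count(M, "M", 2L),
                 adult_age = adult_age, seed = seed),
            class = "analysis_config")
}

strata_of <- function(subjects, config) {
  adult <- subjects$age >= config$adult_age
  list(whole = rep(TRUE, nrow(subjects)),
       adults = adult,
       children = !adult)
}

#' Group-comparison table (descriptives, delta, TOST)
#'
#' For every analysis variable and each stratum (whole sample, adults,
#' children): group sizes, Harrell-Davis median and quartiles per
#' group, Cliff's delta with its asymmetric CI, the two-sided p-value,
#' and the TOST equivalence p-value. Also reports the sex-ratio
#' chi-square (no continuity correction) and Fisher's exact comparison
#' of within-group GMD outlier proportions.
#'
#' @param trials trial table.
#' @param subjects subject table.
#' @param config an [analysis_config()].
#' @return object of class `group_comparison`: `table` (data frame),
#'   `sex_ratio` (`contingency_result`), `outlier_tests` (Fisher
#'   p-values for warm/cool GMD outlier proportions), `summary` (the
#'   per-subject threshold summary with outlier flags).
#' @export
run_group_comparisons <- function(trials, subjects, config =
                                    analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  summ <- summarize_thresholds(trials)
  dat <- merge(subjects, summ, by.x = "id", by.y = "subject_id",
               sort = FALSE)
  dat_flagged <- flag_outliers(
    dat, ifelse(dat$diagnosis == "ASD", "ASD", "TD"))
  qs <- questionnaire_roster()$var
  vars <- c("age", intersect(qs, names(dat)),
            "warm_threshold", "cool_threshold", "warm_gmd", "cool_gmd")
  strata <- strata_of(dat, config)
  rows <- list()
  for (v in vars) {
    for (s in names(strata)) {
      sel <- strata[[s]]
      x <- dat[[v]][sel & dat$diagnosis == "ASD"]
      y <- dat[[v]][sel & dat$diagnosis == "TD"]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      row <- data.frame(variable = v, stratum = s,
                        n_asd = length(x), n_td = length(y),
                        asd_mdn = NA_real_, asd_q1 = NA_real_,
                        asd_q3 = NA_real_, td_mdn = NA_real_,
                        td_q1 = NA_real_, td_q3 = NA_real_,
                        delta = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_h0 = NA_real_,
                        p_equiv = NA_real_, computed = FALSE,
                        stringsAsFactors = FALSE)
      if (length(x) >= 4 && length(y) >= 4) {
        qx <- hd_quantiles(x); qy <- hd_quantiles(y)
        cd <- cliffs_delta(x, y, conf = config$ci_level)
        eq <- delta_tost(x, y, bound = config$delta_bound,
                         alpha = config$alpha)
        row[c("asd_q1", "asd_mdn", "asd_q3")] <- as.list(unname(qx))
        row[c("td_q1", "td_mdn", "td_q3")] <- as.list(unname(qy))
        row$delta <- cd$delta
        row$ci_low <- cd$ci_low; row$ci_high <- cd$ci_high
        row$p_h0 <- cd$p_two_sided
        row$p_equiv <- eq$p_equiv
        row$computed <- TRUE
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  sex_counts <- table(factor(dat$diagnosis, c("ASD", "TD")),
                      factor(dat$sex, c("M", "F")))
  sex_ratio <- chi_square_2x2(sex_counts[1, 1], sex_counts[1, 2],
                              sex_counts[2, 1], sex_counts[2, 2])
  outlier_tests <- list()
  for (v in c("outlier_warm_gmd", "outlier_cool_gmd")) {
    fl <- dat_flagged[[v]]
    asd <- dat_flagged$diagnosis == "ASD"
    a <- sum(fl & asd, na.rm = TRUE)
    b <- sum(!fl & asd, na.rm = TRUE)
    cc <- sum(fl & !asd, na.rm = TRUE)
    d <- sum(!fl & !asd, na.rm = TRUE)
    outlier_tests[[v]] <- list(
      asd_outliers = a, asd_n = a + b, td_outliers = cc, td_n = cc + d,
      fisher_p = fisher_exact_2x2(a, b, cc, d))
  }
  structure(list(table = tab, sex_ratio = sex_ratio,
                 outlier_tests = outlier_tests, summary = dat_flagged),
            class = "group_comparison")
}

#' Spearman correlation matrix with equivalence tests
#'
#' Pairwise Spearman correlations among the given numeric columns
#' (pairwise-complete), each with the Fisher-z test p-value and the
#' TOST equivalence p-value at the configured bound.
#'
#' @param data data frame.
#' @param vars character vector of numeric columns.
#' @param config an [analysis_config()].
#' @return data frame with one row per pair: `var1`, `var2`, `n`,
#'   `r_s`, `p`, `p_equiv`.
#' @export
correlation_table <- function(data, vars, config = analysis_config()) {
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("`data` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    x <- data[[vars[i]]]; y <- data[[vars[j]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    r <- p <- pe <- NA_real_
    if (n >= 4 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      r <- spearman(x[ok], y[ok])
      p <- spearman_test(r, n)$p_two_sided
      pe <- corr_tost(r, n, bound = config$corr_bound,
                      alpha = config$alpha)$p_equiv
    }
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = vars[i], var2 = vars[j], n = n, r_s = r, p = p,
      p_equiv = pe, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Candidate predictor sets per analysis stratum.
regression_candidates <- function(stratum) {
  switch(stratum,
         whole = c("viq", "piq", "srs_t", "srs_item42"),
         adults = c("viq", "piq", "srs_t", "srs_item42",
                    "aasp_low_registration", "aasp_seeking",
                    "aasp_sensitivity", "aasp_avoiding"),
         children = c("viq", "piq", "srs_t", "srs_item42",
                      "sp_low_registration", "sp_seeking",
                      "sp_sensitivity", "sp_avoiding"),
         asd = c("viq", "piq", "srs_t", "srs_item42", "ados_css"),
         stop("unknown stratum: ", stratum, call. = FALSE))
}

#' Hierarchical CPM regressions for warm/cool thresholds
#'
#' For each requested outcome and stratum: step 1 regresses the
#' threshold on diagnosis (ASD = 1), age, sex (male = 1), and
#' counterbalance order (warm first = 1); step 2 adds the best
#' BIC-selected subset of stratum-specific candidate predictors; step 3
#' appends the matching GMD. When covariates are missing and
#' `impute = TRUE`, the candidate search minimizes the across-imputation
#' mean BIC and the step fits are pooled by Rubin's rules.
#'
#' @param trials trial table.
#' @param subjects subject table.
#' @param config an [analysis_config()].
#' @param strata subset of `c("whole", "adults", "children", "asd")`.
#' @param outcomes subset of `c("warm", "cool")`.
#' @param impute impute missing covariates (default TRUE)? With FALSE,
#'   complete cases are used.
#' @return object of class `regression_report`: nested list
#'   `results[[outcome]][[stratum]]`, each a `cpm_hierarchy` (complete
#'   data) or a list with per-imputation hierarchies plus pooled
#'   coefficient tables.
#' @export
run_regressions <- function(trials, subjects, config = analysis_config(),
                            strata = "whole",
                            outcomes = c("warm", "cool"),
                            impute = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  summ <- summarize_thresholds(trials)
  dat <- merge(subjects, summ, by.x = "id", by.y = "subject_id",
               sort = FALSE)
  dat$diagnosis_asd <- as.numeric(dat$diagnosis == "ASD")
  dat$sex_male <- as.numeric(dat$sex == "M")
  dat$counterbalance_warm_first <-
    as.numeric(dat$counterbalance == "warm_first")
  baseline_all <- c("diagnosis_asd", "age", "sex_male",
                    "counterbalance_warm_first")
  results <- list()
  for (outc in outcomes) {
    ycol <- paste0(outc, "_threshold")
    gcol <- paste0(outc, "_gmd")
    results[[outc]] <- list()
    for (s in strata) {
      sel <- if (s == "asd") dat$diagnosis == "ASD"
             else strata_of(dat, config)[[s]]
      sub <- dat[sel & is.finite(dat[[ycol]]) & is.finite(dat[[gcol]]), ,
                 drop = FALSE]
      baseline <- if (s == "asd") setdiff(baseline_all, "diagnosis_asd")
                  else baseline_all
      cand <- intersect(regression_candidates(s), names(sub))
      cols <- c(baseline, cand, gcol)
      any_missing <- anyNA(sub[, cols])
      if (!any_missing || !impute) {
        cc <- stats::complete.cases(sub[, cols])
        sub_cc <- sub[cc, , drop = FALSE]
        hier <- hierarchical_models(sub_cc[[ycol]], sub_cc, baseline,
                                    cand, gcol)
        results[[outc]][[s]] <- hier
      } else {
        imp <- pmm_multiple_impute(
          sub[, c(cols, ycol)], M = config$M, seed = config$seed,
          exclude = c(ycol, gcol))
        # candidate selection on across-imputation mean BIC
        sels <- lapply(imp$datasets, function(d)
          best_subset_bic(d[[ycol]],
                          as.matrix(d[, baseline, drop = FALSE]),
                          d[, cand, drop = FALSE]))
        bics <- sapply(sels, function(sl)
          sl$table$bic[order(sl$table$id)])
        ids <- sort(sels[[1]]$table$id)
        models <- sels[[1]]$table$model[order(sels[[1]]$table$id)]
        mean_bic <- rowMeans(matrix(bics, ncol = length(sels)))
        w <- exp(-(mean_bic - min(mean_bic)) / 2)
        w <- w / sum(w)
        best <- which.min(mean_bic)
        kept <- if (nzchar(models[best]))
          strsplit(models[best], "+", fixed = TRUE)[[1]] else character(0)
        hiers <- lapply(imp$datasets, function(d) {
          fit1 <- fit_cpm(d[[ycol]],
                          as.matrix(d[, baseline, drop = FALSE]))
          fit2 <- fit_cpm(d[[ycol]],
                          as.matrix(d[, c(baseline, kept),
                                      drop = FALSE]))
          fit3 <- fit_cpm(d[[ycol]],
                          as.matrix(d[, c(baseline, kept, gcol),
                                      drop = FALSE]))
          list(step1 = fit1, step2 = fit2, step3 = fit3)
        })
        pooled <- lapply(c(step1 = "step1", step2 = "step2",
                           step3 = "step3"), function(st)
          pool_rubin(lapply(hiers, `[[`, st)))
        r2 <- sapply(c("step1", "step2", "step3"), function(st)
          mean(sapply(hiers, function(h)
            model_inference(h[[st]])$nagelkerke_r2)))
        results[[outc]][[s]] <- list(
          kind = "imputed", M = imp$M, selected = kept,
          mean_bic = data.frame(model = models, bic = mean_bic,
                                weight = w, stringsAsFactors = FALSE),
          pooled = pooled, mean_r2 = r2,
          delta_r2 = c(step2 = unname(r2[2] - r2[1]),
                       step3 = unname(r2[3] - r2[2])),
          fits = hiers)
      }
    }
  }
  structure(list(results = results, strata = strata,
                 outcomes = outcomes, config = config),
            class = "regression_report")
}
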