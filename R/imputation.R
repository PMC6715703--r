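#' Multiple imputation by predictive mean matching
#'
#' Produces `M` completed copies of a data frame whose covariates have
#' missing values. For each imputation the rows are bootstrapped, each
#' incomplete numeric variable is regressed (ordinary least squares, on
#' a complete-case basis) on a numeric basis of the other variables,
#' and every missing cell is filled with the observed value of a donor
#' drawn at random from the `k` observed rows with the nearest
#' predicted means. Imputed values therefore always belong to the
#' observed support of their variable, and non-missing cells are
#' identical across the `M` datasets.
#'
#' @param data data frame; missingness must be confined to numeric
#'   covariate columns (character/factor columns may not contain `NA`
#'   unless listed in `exclude`).
#' @param M number of imputations (default 20).
#' @param seed optional integer seed (RNG state restored).
#' @param k donor-pool size for the nearest-prediction draw (default 3).
#' @param exclude columns never to impute (e.g. outcomes). They still
#'   enter the imputation model as predictors, which is essential for
#'   unbiased covariate-outcome associations after imputation.
#' @return object of class `imputation_set`: `datasets` (list of `M`
#'   completed data frames), `M`, `k`, `seed`, `imputed_vars`.
#' @export
pmm_multiple_impute <- function(data, M = 20L, seed = NULL, k = 3L,
                                exclude = NULL) {
  stopifnot(is.data.frame(data))
  M <- check_count(M, "M", 2L)
  k <- check_count(k, "k", 1L)
  use <- names(data)
  targets <- setdiff(use, exclude)
  incomplete <- targets[vapply(targets, function(v) anyNA(data[[v]]),
                               logical(1))]
  non_num <- incomplete[!vapply(incomplete, function(v)
    is.numeric(data[[v]]), logical(1))]
  if (length(non_num))
    stop("non-numeric column(s) with missing values: ",
         paste(non_num, collapse = ", "), call. = FALSE)
  for (v in incomplete) {
    n_obs <- sum(!is.na(data[[v]]))
    if (n_obs == 0)
      stop("variable `", v, "` has no observed values", call. = FALSE)
    if (n_obs < 10)
      stop("variable `", v, "` has fewer than 10 observed donors",
           call. = FALSE)
  }
  if (!length(incomplete)) {
    return(structure(list(datasets = rep(list(data), M), M = M, k = k,
                          seed = seed, imputed_vars = character(0)),
                     class = "imputation_set"))
  }
  # numeric predictor basis: numeric columns as-is, char/factor as dummies
  basis_of <- function(df, drop_var) {
    cols <- setdiff(use, drop_var)
    parts <- lapply(cols, function(v) {
      x <- df[[v]]
      if (is.numeric(x)) {
        m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
      } else {
        levs <- sort(unique(as.character(data[[v]][!is.na(data[[v]])])))
        if (length(levs) < 2) return(NULL)
        m <- vapply(levs[-1], function(l) as.numeric(as.character(x) == l),
                    numeric(nrow(df)))
        m <- matrix(m, nrow = nrow(df),
                    dimnames = list(NULL, paste0(v, "_", levs[-1])))
      }
      m
    })
    do.call(cbind, parts[!vapply(parts, is.null, logical(1))])
  }
  n <- nrow(data)
  datasets <- with_seed(seed, {
    lapply(seq_len(M), function(m) {
      boot <- sample.int(n, n, replace = TRUE)
      completed <- data
      for (v in incomplete) {
        miss_rows <- which(is.na(data[[v]]))
        obs_rows <- which(!is.na(data[[v]]))
        Xall <- basis_of(data, v)
        fitted_ok <- FALSE
        if (!is.null(Xall)) {
          # fit on bootstrap complete cases; predict everywhere with
          # remaining predictor gaps filled by observed column means
          yb <- data[[v]][boot]
          Xb <- Xall[boot, , drop = FALSE]
          cc <- which(!is.na(yb) & stats::complete.cases(Xb))
          if (length(cc) >= ncol(Xb) + 2) {
            fit <- tryCatch(
              stats::lm.fit(cbind(1, Xb[cc, , drop = FALSE]), yb[cc]),
              error = function(e) NULL)
            if (!is.null(fit) && all(is.finite(fit$coefficients[
              !is.na(fit$coefficients)]))) {
              cf <- fit$coefficients
              cf[is.na(cf)] <- 0
              Xfill <- Xall
              for (jj in seq_len(ncol(Xfill))) {
                nas <- is.na(Xfill[, jj])
                if (any(nas))
                  Xfill[nas, jj] <- mean(Xfill[, jj], na.rm = TRUE)
              }
              pred <- drop(cbind(1, Xfill) %*% cf)
              if (all(is.finite(pred))) {
                fitted_ok <- TRUE
                pred_obs <- pred[obs_rows]
                for (r in miss_rows) {
                  donors <- obs_rows[order(abs(pred_obs - pred[r]))[
                    seq_len(min(k, length(obs_rows)))]]
                  completed[[v]][r] <- data[[v]][sample(donors, 1)]
                }
              }
            }
          }
        }
        if (!fitted_ok) {
          warning("degenerate PMM regression for `", v,
                  "`; falling back to random donors", call. = FALSE)
          completed[[v]][miss_rows] <- data[[v]][
            sample(obs_rows, length(miss_rows), replace = TRUE)]
        }
      }
      completed
    })
  })
  structure(list(datasets = datasets, M = M, k = k, seed = seed,
                 imputed_vars = incomplete),
            class = "imputation_set")
}

#' Rubin's-rules pooling of repeated fits
#'
#' Pools coefficient estimates from `M` fits of an identically
#' specified model on multiply-imputed datasets: pooled estimate is the
#' mean, total variance `T = W + (1 + 1/M) B` with `W` the mean
#' within-imputation variance and `B` the between-imputation variance
#' of the estimates; inference uses the large-sample normal reference.
#'
#' @param fits list (length >= 2) of `cpm_fit` objects, or of lists
#'   with elements `coef` (named numeric) and `se` (named numeric).
#' @return object of class `pooled_estimate`: data frame `table` with
#'   one row per coefficient (`estimate`, `within_var`, `between_var`,
#'   `total_var`, `se`, `z`, `p`), plus `M`.
#' @export
pool_rubin <- function(fits) {
  if (!is.list(fits) || length(fits) < 2)
    stop("`fits` must be a list of at least 2 fits", call. = FALSE)
  get_cf <- function(f) {
    if (inherits(f, "cpm_fit")) list(coef = f$beta, se = f$se_beta)
    else if (is.list(f) && all(c("coef", "se") %in% names(f))) f
    else stop("unsupported fit object in `fits`", call. = FALSE)
  }
  parts <- lapply(fits, get_cf)
  nm <- names(parts[[1]]$coef)
  for (p in parts)
    if (!identical(names(p$coef), nm))
      stop("fits have mismatched coefficient sets", call. = FALSE)
  M <- length(parts)
  est <- sapply(parts, function(p) p$coef)
  ses <- sapply(parts, function(p) p$se)
  est <- matrix(est, ncol = M)
  ses <- matrix(ses, ncol = M)
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- apply(est, 1, var)
  Tv <- W + (1 + 1 / M) * B
  z <- qbar / sqrt(Tv)
  tab <- data.frame(coefficient = nm, estimate = qbar, within_var = W,
                    between_var = B, total_var = Tv, se = sqrt(Tv),
                    z = z, p = 2 * pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, M = M), class = "pooled_estimate")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("PMM multiple imputation: M = %d, k = %d, variables: %s\n",
              x$M, x$k,
              if (length(x$imputed_vars))
                paste(x$imputed_vars, collapse = ", ") else "(none)"))
  invisible(x)
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Rubin's-rules pooled estimates (M = %d):\n", x$M))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
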