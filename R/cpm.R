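#' Fit a cumulative probability model (proportional-odds CPM)
#'
#' Semi-parametric proportional-odds regression for a continuous (or
#' ordinal) outcome: every distinct outcome value defines an ordered
#' category, and `P(Y >= y_(j) | X) = plogis(alpha_j + X beta)` with
#' strictly decreasing intercepts `alpha_j`. With no covariates the
#' model is saturated and the intercepts reproduce the empirical
#' exceedance logits; with a single binary covariate the slope test
#' behaves like a Wilcoxon-Mann-Whitney comparison. The likelihood is
#' maximized by a damped Newton method (analytic gradient and Hessian;
#' the intercept block of the Hessian is tridiagonal, so each step costs
#' O(J + p^3)). Steps are halved until the log-likelihood increases and
#' the intercepts stay monotone.
#'
#' @param y numeric outcome vector (>= 2 distinct values).
#' @param X covariate matrix or data frame (no intercept column), or
#'   `NULL` for an intercept-only fit. Must be full column rank.
#' @param tol convergence tolerance on the max absolute gradient
#'   (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return object of class `cpm_fit`: `alpha` (J-1 intercepts, ordered
#'   decreasing), `beta` (named slopes), `se_beta`, `vcov_beta`,
#'   `vcov` (full, only when J - 1 + p <= 400), `loglik`, `loglik_null`
#'   (intercept-only), `n`, `J`, `y_values`, `converged`, `iter`.
#' @export
fit_cpm <- function(y, X = NULL, tol = 1e-8, max_iter = 100L) {
  y <- check_numeric_vec(y, "y", 2L)
  n <- length(y)
  if (is.null(X)) {
    Xm <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    if (is.data.frame(X)) Xm <- as.matrix(X) else Xm <- as.matrix(X)
    storage.mode(Xm) <- "double"
    if (nrow(Xm) != n)
      stop("`X` must have one row per outcome value", call. = FALSE)
    if (any(!is.finite(Xm)))
      stop("`X` contains non-finite values", call. = FALSE)
    if (is.null(colnames(Xm)))
      colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
  }
  p <- ncol(Xm)
  # the intercepts play the role of a free constant, so X must be full
  # rank jointly with an intercept column
  if (p > 0 && qr(cbind(1, Xm))$rank < p + 1L)
    stop("`X` is rank deficient", call. = FALSE)
  yv <- sort(unique(y))
  J <- length(yv)
  if (J < 2) stop("`y` must take at least 2 distinct values", call. = FALSE)
  if (n <= p)
    stop("more covariates than observations", call. = FALSE)
  cat_i <- match(y, yv)
  counts <- tabulate(cat_i, J)
  cum_ge <- rev(cumsum(rev(counts)))        # cum_ge[j] = #{y >= yv[j]}
  loglik_null <- sum(counts * log(counts / n))

  theta <- qlogis(cum_ge[2:J] / n)          # empirical exceedance logits
  beta <- numeric(p)

  upper_idx <- cat_i - 1L                   # theta index of the upper term
  lower_idx <- cat_i                        # theta index of the lower term
  has_upper <- cat_i >= 2L
  has_lower <- cat_i <= J - 1L

  eval_model <- function(theta, beta, want_deriv = TRUE) {
    eta <- if (p > 0) drop(Xm %*% beta) else numeric(n)
    A <- rep(1, n); B <- rep(0, n)
    A[has_upper] <- plogis(theta[upper_idx[has_upper]] + eta[has_upper])
    B[has_lower] <- plogis(theta[lower_idx[has_lower]] + eta[has_lower])
    P <- A - B
    if (any(P <= 0)) return(list(ll = -Inf))
    ll <- sum(log(P))
    if (!want_deriv) return(list(ll = ll))
    fA <- ifelse(has_upper, A * (1 - A), 0)
    fB <- ifelse(has_lower, B * (1 - B), 0)
    gA <- fA / P
    gB <- -fB / P
    fpA <- fA * (1 - 2 * A)
    fpB <- fB * (1 - 2 * B)
    hAA <- fpA / P - gA^2
    hBB <- -fpB / P - (fB / P)^2
    hAB <- fA * fB / P^2
    m <- J - 1L
    g_theta <- sum_by(gA[has_upper], upper_idx[has_upper], m) +
      sum_by(gB[has_lower], lower_idx[has_lower], m)
    # tridiagonal theta-block of the Hessian
    h_diag <- sum_by(hAA[has_upper], upper_idx[has_upper], m) +
      sum_by(hBB[has_lower], lower_idx[has_lower], m)
    both <- has_upper & has_lower           # categories 2..J-1
    h_off <- sum_by(hAB[both], upper_idx[both], max(m - 1L, 0L))
    out <- list(ll = ll, g_theta = g_theta, h_diag = h_diag, h_off = h_off)
    if (p > 0) {
      wA <- hAA + hAB                        # d2/(dtheta_upper dbeta) weight
      wB <- hBB + hAB
      out$g_beta <- drop(crossprod(Xm, gA + gB))
      Umat <- matrix(0, m, p)
      if (any(has_upper))
        Umat <- Umat + rowsum_mat(Xm[has_upper, , drop = FALSE] *
                                    wA[has_upper],
                                  upper_idx[has_upper], m)
      if (any(has_lower))
        Umat <- Umat + rowsum_mat(Xm[has_lower, , drop = FALSE] *
                                    wB[has_lower],
                                  lower_idx[has_lower], m)
      out$U <- Umat
      out$Q <- crossprod(Xm * (hAA + 2 * hAB + hBB), Xm)
    }
    out
  }

  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  ev <- eval_model(theta, beta)
  ll <- ev$ll
  while (iter < max_iter) {
    iter <- iter + 1L
    gmax <- max(abs(c(ev$g_theta, if (p > 0) ev$g_beta)))
    if (gmax < tol) { converged <- TRUE; break }
    # Newton step: solve M s = g with M = -H (positive definite near MLE)
    d <- -ev$h_diag
    e <- if (J > 2) -ev$h_off else numeric(0)
    # M = -H has theta block (d, e) tridiagonal, off block -U, beta
    # block -Q; solve M s = g by Schur complement on the beta block.
    step <- tryCatch({
      if (p > 0) {
        TiU <- tridiag_solve(d, e, cbind(ev$U, ev$g_theta))
        Ti_g <- TiU[, p + 1L]
        TiUo <- TiU[, seq_len(p), drop = FALSE]
        S <- -ev$Q - crossprod(ev$U, TiUo)
        s_beta <- solve(S, ev$g_beta + drop(crossprod(ev$U, Ti_g)))
        s_theta <- Ti_g + TiUo %*% s_beta
        list(theta = drop(s_theta), beta = drop(s_beta))
      } else {
        list(theta = drop(tridiag_solve(d, e, matrix(ev$g_theta))),
             beta = numeric(0))
      }
    }, error = function(e) NULL)
    if (is.null(step)) break
    gdot <- sum(c(ev$g_theta, if (p > 0) ev$g_beta) *
                  c(step$theta, step$beta))
    lam <- 1
    improved <- FALSE
    for (h in 1:40) {
      th_new <- theta + lam * step$theta
      be_new <- beta + lam * step$beta
      if (all(diff(th_new) < 0)) {
        ev_new <- eval_model(th_new, be_new)
        # Armijo sufficient-increase condition
        if (is.finite(ev_new$ll) &&
            ev_new$ll >= ll + 1e-4 * lam * gdot) {
          theta <- th_new; beta <- be_new
          improved <- ev_new$ll > ll
          ll <- ev_new$ll
          ev <- ev_new
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved) {
      if (max(abs(c(ev$g_theta, if (p > 0) ev$g_beta))) < 1e-4)
        converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter)
    warning("CPM did not converge in ", max_iter, " iterations",
            call. = FALSE)
  if (p > 0 && any(abs(beta) > 30))
    warning("extreme coefficient estimates; possible complete separation",
            call. = FALSE)

  vcov_beta <- matrix(NA_real_, p, p)
  se_beta <- rep(NA_real_, p)
  vcov_full <- NULL
  if (p > 0) {
    d <- -ev$h_diag
    e <- if (J > 2) -ev$h_off else numeric(0)
    vb <- tryCatch({
      TiU <- tridiag_solve(d, e, ev$U)
      solve(-ev$Q - crossprod(ev$U, TiU))
    }, error = function(e) matrix(NA_real_, p, p))
    vcov_beta <- vb
    se_beta <- sqrt(pmax(diag(vb), 0))
    names(se_beta) <- colnames(Xm)
    dimnames(vcov_beta) <- list(colnames(Xm), colnames(Xm))
  }
  if (J - 1L + p <= 400L) {
    M <- matrix(0, J - 1L + p, J - 1L + p)
    m <- J - 1L
    diag(M)[seq_len(m)] <- -ev$h_diag
    if (m > 1) {
      idx <- seq_len(m - 1L)
      M[cbind(idx, idx + 1L)] <- -ev$h_off
      M[cbind(idx + 1L, idx)] <- -ev$h_off
    }
    if (p > 0) {
      M[seq_len(m), m + seq_len(p)] <- -ev$U
      M[m + seq_len(p), seq_len(m)] <- t(-ev$U)
      M[m + seq_len(p), m + seq_len(p)] <- -ev$Q
    }
    vcov_full <- tryCatch(solve(M), error = function(e) NULL)
  }
  beta_named <- beta
  if (p > 0) names(beta_named) <- colnames(Xm)
  structure(list(alpha = theta, beta = beta_named, se_beta = se_beta,
                 vcov_beta = vcov_beta, vcov = vcov_full,
                 loglik = ll, loglik_null = loglik_null, n = n, J = J,
                 y_values = yv, converged = converged, iter = iter,
                 predictors = colnames(Xm)),
            class = "cpm_fit")
}

# Solve the symmetric positive-definite tridiagonal system T x = B
# (diag `d`, off-diagonal `e`) for each column of B, by LDL^T sweeps.
tridiag_solve <- function(d, e, B) {
  m <- length(d)
  B <- as.matrix(B)
  if (m == 1L) return(B / d[1])
  l <- numeric(m - 1L)
  dd <- numeric(m)
  dd[1] <- d[1]
  for (i in seq_len(m - 1L)) {
    if (dd[i] <= 0) stop("tridiagonal system not positive definite")
    l[i] <- e[i] / dd[i]
    dd[i + 1L] <- d[i + 1L] - l[i] * e[i]
  }
  if (dd[m] <= 0) stop("tridiagonal system not positive definite")
  # forward: L z = B
  Z <- B
  for (i in seq_len(m - 1L))
    Z[i + 1L, ] <- Z[i + 1L, ] - l[i] * Z[i, ]
  Z <- Z / dd
  # backward: L^T x = z
  for (i in rev(seq_len(m - 1L)))
    Z[i, ] <- Z[i, ] - l[i] * Z[i + 1L, ]
  Z
}

# Row-group sums of a matrix: rows of `m` summed by integer group `g`
# (values in 1..len), zero rows for empty groups.
rowsum_mat <- function(m, g, len) {
  out <- matrix(0, len, ncol(m))
  r <- rowsum(m, g)
  out[as.integer(rownames(r)), ] <- r
  out
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat(sprintf("Cumulative probability model: n = %d, J = %d, logLik = %.3f%s\n",
              x$n, x$J, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  if (length(x$beta)) {
    tab <- data.frame(beta = x$beta, se = x$se_beta,
                      z = x$beta / x$se_beta)
    print(round(tab, 4))
  }
  invisible(x)
}

#' @export
logLik.cpm_fit <- function(object, ...) {
  structure(object$loglik,
            df = object$J - 1L + length(object$beta),
            nobs = object$n, class = "logLik")
}

#' @export
coef.cpm_fit <- function(object, ...) object$beta

#' @export
vcov.cpm_fit <- function(object, ...) object$vcov_beta
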