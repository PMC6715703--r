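test_that("binary-outcome CPM equals logistic regression", {
  set.seed(701)
  for (rep in 1:3) {
    n <- 150
    X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.5)))
    fit <- fit_cpm(y, X)
    ref <- glm(y ~ X, family = binomial)
    expect_equal(unname(fit$beta), unname(coef(ref)[-1]),
                 tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
    expect_equal(unname(fit$se_beta),
                 unname(sqrt(diag(vcov(ref))[-1])), tolerance = 1e-3)
  }
})

test_that("intercept-only CPM reproduces empirical exceedance logits", {
  set.seed(702)
  y <- sample(c(1.1, 2.3, 2.3, 4.7, 5.2, 5.2, 5.2, 8.0), 40,
              replace = TRUE)
  fit <- fit_cpm(y)
  yv <- sort(unique(y))
  emp <- qlogis(vapply(yv[-1], function(v) mean(y >= v), numeric(1)))
  expect_equal(fit$alpha, emp, tolerance = 1e-10)
  expect_equal(fit$loglik, fit$loglik_null, tolerance = 1e-10)
})

test_that("CPM is invariant to monotone transforms of the outcome", {
  set.seed(703)
  x <- rnorm(150)
  y <- exp(0.7 * x + rlogis(150) / 2)
  f1 <- fit_cpm(y, cbind(x = x))
  f2 <- fit_cpm(rank(y), cbind(x = x))
  f3 <- fit_cpm(log(y), cbind(x = x))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$beta, f3$beta, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  # reversing the outcome negates the slope
  f4 <- fit_cpm(-y, cbind(x = x))
  expect_equal(f4$beta, -f1$beta, tolerance = 1e-6)
})

test_that("CPM intercepts are strictly decreasing and J <= n", {
  set.seed(704)
  x <- rnorm(80)
  y <- 0.5 * x + rnorm(80)
  fit <- fit_cpm(y, cbind(x = x))
  expect_true(all(diff(fit$alpha) < 0))
  expect_lte(fit$J, fit$n)
  expect_true(fit$converged)
})

test_that("CPM recovers a known slope within sampling error", {
  set.seed(705)
  n <- 800
  x <- rnorm(n)
  y <- qlogis(plogis(1.0 * x + rlogis(n)))  # latent-logistic CPM with beta 1
  fit <- fit_cpm(y, cbind(x = x))
  expect_lt(abs(fit$beta - 1) / fit$se_beta, 3)
})

test_that("CPM input validation and degenerate cases", {
  expect_error(fit_cpm(rep(1, 10)), "distinct")
  expect_error(fit_cpm(1:10, matrix(rnorm(20), 2)), "one row per")
  expect_error(fit_cpm(1:10, cbind(a = 1:10, b = 2 * (1:10))),
               "rank deficient")
  expect_warning(
    fit_cpm(c(rep(0, 10), rep(1, 10)), cbind(x = c(rep(0, 10), rep(1, 10)))),
    "separation|converge")
})

test_that("CPM LR p-value tracks the Wilcoxon-Mann-Whitney test", {
  set.seed(706)
  diffs <- replicate(25, {
    g <- rep(0:1, each = 50)
    y <- rnorm(100) + 0.3 * g
    fit <- fit_cpm(y, cbind(g = g))
    st <- model_inference(fit)
    pw <- wilcox.test(y[g == 1], y[g == 0], exact = FALSE,
                      correct = FALSE)$p.value
    st$p - pw
  })
  expect_lt(median(abs(diffs)), 0.015)
})

test_that("model_inference computes LR, Nagelkerke R2, and Wald table", {
  set.seed(707)
  x <- rnorm(120)
  y <- 0.8 * x + rlogis(120)
  fit <- fit_cpm(y, cbind(x = x))
  st <- model_inference(fit)
  expect_gte(st$lr_chi2, 0)
  expect_equal(st$df, 1)
  expect_gte(st$nagelkerke_r2, 0)
  expect_lte(st$nagelkerke_r2, 1)
  # identical models: LR = 0, R2 = 0
  st0 <- model_inference(fit, fit)
  expect_equal(st0$lr_chi2, 0)
  expect_equal(st0$nagelkerke_r2, 0)
  # Wald CI excludes 1 exactly when Wald p < 0.05
  ct <- st$coef_table
  expect_equal(ct$aor_low > 1 | ct$aor_high < 1, ct$p < 0.05)
  # Wald and LR chi-squares agree asymptotically for one strong predictor
  expect_equal(ct$wald_chi2, st$lr_chi2, tolerance = 0.1 * st$lr_chi2)
})

test_that("model_inference rejects non-nested fits", {
  set.seed(708)
  x <- rnorm(50); y <- x + rlogis(50)
  f1 <- fit_cpm(y, cbind(a = x))
  f2 <- fit_cpm(y[-1], cbind(a = x[-1]))
  expect_error(model_inference(f1, f2), "same outcome")
})

test_that("best_subset_bic weights and inclusion probabilities", {
  set.seed(709)
  n <- 300
  x_true <- rnorm(n)
  x_null <- rnorm(n)
  y <- 1.5 * x_true + rlogis(n)
  sel <- best_subset_bic(y, NULL,
                         cbind(strong = x_true, nil = x_null))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_gte(min(sel$table$evidence_ratio), 1)
  expect_gt(sel$inclusion_probs[["strong"]], 0.95)
  expect_lt(sel$inclusion_probs[["nil"]], 0.5)
  expect_true(grepl("strong", sel$best_model))
})

test_that("duplicate candidates share weight equally", {
  set.seed(710)
  x <- rnorm(120)
  y <- x + rlogis(120)
  sel <- best_subset_bic(y, NULL, cbind(a = x, b = x + 0))
  tab <- sel$table
  wa <- tab$weight[tab$model == "a"]
  wb <- tab$weight[tab$model == "b"]
  expect_equal(wa, wb, tolerance = 1e-10)
})

test_that("hierarchical_models: steps, determinism, GMD attenuation", {
  set.seed(711)
  n <- 250
  g <- rep(0:1, length.out = n)
  age <- runif(n, 8, 50)
  sexm <- rbinom(n, 1, 0.6)
  cb <- rbinom(n, 1, 0.5)
  noise_sd <- exp(0.5 * g + rnorm(n, 0, 0.3))   # group raises variability
  y <- 1.2 * noise_sd + rlogis(n) * 0.3         # threshold driven by GMD only
  dat <- data.frame(diagnosis_asd = g, age = age, sex_male = sexm,
                    counterbalance_warm_first = cb,
                    viq = rnorm(n, 100, 12), piq = rnorm(n, 100, 12),
                    gmdcol = noise_sd)
  h <- hierarchical_models(y, dat,
                           baseline = c("diagnosis_asd", "age",
                                        "sex_male",
                                        "counterbalance_warm_first"),
                           candidates = c("viq", "piq"),
                           gmd_col = "gmdcol")
  # step 3 adds the variable that actually generates y
  expect_gt(h$delta_r2[["step3"]], 0.05)
  # the diagnosis odds ratio attenuates toward 1 once GMD is in
  b2 <- h$fits$step2$beta[["diagnosis_asd"]]
  b3 <- h$fits$step3$beta[["diagnosis_asd"]]
  expect_lt(abs(b3), abs(b2))
  # determinism: same data, same fits
  h2 <- hierarchical_models(y, dat,
                            baseline = c("diagnosis_asd", "age",
                                         "sex_male",
                                         "counterbalance_warm_first"),
                            candidates = c("viq", "piq"),
                            gmd_col = "gmdcol")
  expect_identical(h$fits$step3$beta, h2$fits$step3$beta)
  # LR is additive along the nested chain
  lr_direct <- model_inference(h$fits$step3, h$fits$step1)$lr_chi2
  lr_sum <- model_inference(h$fits$step2, h$fits$step1)$lr_chi2 +
    model_inference(h$fits$step3, h$fits$step2)$lr_chi2
  expect_equal(lr_direct, lr_sum, tolerance = 1e-6)
})

test_that("a constant GMD column adds nothing at step 3", {
  set.seed(712)
  n <- 120
  dat <- data.frame(diagnosis_asd = rep(0:1, n / 2), age = runif(n, 8, 50),
                    sex_male = rbinom(n, 1, 0.5),
                    counterbalance_warm_first = rbinom(n, 1, 0.5),
                    viq = rnorm(n), gmdcol = 1)
  y <- 0.3 * dat$diagnosis_asd + rlogis(n)
  # a constant column carries no information (it is collinear with the
  # intercepts); it is dropped with a warning and step 3 adds nothing
  expect_warning(
    h <- hierarchical_models(y, dat, baseline = c("diagnosis_asd", "age"),
                             candidates = "viq", gmd_col = "gmdcol"),
    "dropped")
  expect_equal(h$delta_r2[["step3"]], 0, tolerance = 1e-10)
})
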