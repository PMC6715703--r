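test_that("hd_quantile matches trivial cases and the Beta-CDF oracle", {
  expect_equal(hd_quantile(5.0, 0.5)$estimate, 5.0)
  # n = 2, q = 0.5: Beta(1.5, 1.5) symmetry gives equal weights
  expect_equal(hd_quantile(c(0, 1), 0.5)$estimate, 0.5)
  expect_equal(hd_quantile(c(1, 2, 3, 10), 0.5)$estimate,
               hd_oracle(c(1, 2, 3, 10), 0.5), tolerance = 1e-10)
  set.seed(401)
  for (rep in 1:20) {
    x <- rnorm(sample(3:15, 1), sd = 3)
    q <- runif(1, 0.05, 0.95)
    expect_equal(hd_quantile(x, q)$estimate, hd_oracle(x, q),
                 tolerance = 1e-10)
  }
})

test_that("hd_quantile weights are a proper convex combination", {
  set.seed(402)
  for (rep in 1:10) {
    x <- rexp(sample(2:20, 1))
    h <- hd_quantile(x, runif(1, 0.1, 0.9))
    expect_equal(sum(h$weights), 1, tolerance = 1e-12)
    expect_true(all(h$weights >= 0))
    expect_gte(h$estimate, min(x))
    expect_lte(h$estimate, max(x))
  }
})

test_that("hd_quantile is affine-equivariant and reflection-symmetric", {
  set.seed(403)
  for (rep in 1:10) {
    x <- rlnorm(12)
    q <- runif(1, 0.1, 0.9)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(hd_quantile(a * x + b, q)$estimate,
                 a * hd_quantile(x, q)$estimate + b, tolerance = 1e-10)
    # reflecting the sample swaps q and 1 - q
    expect_equal(hd_quantile(-x, q)$estimate,
                 -hd_quantile(x, 1 - q)$estimate, tolerance = 1e-10)
  }
})

test_that("hd_quantile rejects bad input", {
  expect_error(hd_quantile(numeric(0), 0.5), "at least")
  expect_error(hd_quantile(c(1, NA), 0.5), "non-finite")
  expect_error(hd_quantile(1:3, 0), "strictly inside")
  expect_error(hd_quantile(1:3, 1), "strictly inside")
})

test_that("gmd matches enumeration and scales correctly", {
  expect_equal(gmd(c(3, 3, 3, 3)), 0)
  expect_equal(gmd(c(0, 1)), 1)
  expect_equal(gmd(c(1, 2, 4)), 2)
  set.seed(404)
  for (rep in 1:15) {
    x <- rnorm(sample(2:50, 1), sd = 5)
    expect_equal(gmd(x), gmd_oracle(x), tolerance = 1e-12)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(gmd(a * x + b), abs(a) * gmd(x), tolerance = 1e-10)
  }
  # n = 2 identity: gmd equals twice the mean absolute deviation
  x <- c(1.3, 4.1)
  expect_equal(gmd(x), 2 * mean(abs(x - mean(x))))
  expect_error(gmd(3), "at least 2")
})

test_that("threshold_change converts temperatures by modality", {
  expect_equal(threshold_change(33.88, "warm"), 1.88)
  expect_equal(threshold_change(29.59, "cool"), 2.41)
  expect_equal(threshold_change(32, "warm"), 0)
  expect_equal(threshold_change(32, "cool"), 0)
  expect_equal(threshold_change(c(33, 31), c("warm", "cool")), c(1, 1))
  expect_error(threshold_change(50.1, "warm"), "bounds")
  expect_error(threshold_change(-0.5, "cool"), "bounds")
  expect_error(threshold_change(33, "hot"), "modality")
})

test_that("summarize_subject pools blocks and handles missing modality", {
  trials <- data.frame(
    subject_id = "s1",
    modality = rep("warm", 10), block = rep(1:2, each = 5),
    trial = rep(1:5, 2), temperature = rep(34, 10))
  s <- summarize_subject(trials)
  expect_equal(s$warm_threshold, 2.0)
  expect_equal(s$warm_gmd, 0)
  expect_true(is.na(s$cool_threshold))
  expect_equal(s$n_cool, 0L)

  # block structure: changes 1/1/2/2/3 in each block
  tr2 <- data.frame(
    subject_id = "s2",
    modality = rep("warm", 10), block = rep(1:2, each = 5),
    trial = rep(1:5, 2), temperature = rep(c(33, 33, 34, 34, 35), 2))
  s2 <- summarize_subject(tr2)
  ch <- rep(c(1, 1, 2, 2, 3), 2)
  expect_equal(s2$warm_threshold, hd_oracle(ch, 0.5), tolerance = 1e-10)
  expect_equal(s2$warm_block1, hd_oracle(c(1, 1, 2, 2, 3), 0.5),
               tolerance = 1e-10)
  expect_equal(s2$warm_block1, s2$warm_block2)
})

test_that("icc_consistency_avg behaves per its definition", {
  set.seed(405)
  b1 <- rnorm(40, 2, 1)
  expect_equal(icc_consistency_avg(b1, b1)$icc, 1)
  # consistency form ignores fixed block shifts
  expect_equal(icc_consistency_avg(b1, b1 + 0.7)$icc, 1)
  # independent columns: icc near 0
  r <- replicate(20, {
    icc_consistency_avg(rnorm(200), rnorm(200))$icc
  })
  expect_lt(abs(mean(r)), 0.15)
  # degenerate: no between-subject variance
  d <- icc_consistency_avg(rep(1, 5), rep(1, 5))
  expect_true(d$degenerate)
})

test_that("icc confidence interval brackets the estimate", {
  set.seed(406)
  subj <- rnorm(60, 0, 2)
  b1 <- subj + rnorm(60, 0, 0.5)
  b2 <- subj + rnorm(60, 0, 0.5)
  r <- icc_consistency_avg(b1, b2)
  expect_lt(r$ci_low, r$icc)
  expect_gt(r$ci_high, r$icc)
  expect_lte(r$ci_high, 1)
})

test_that("boxplot rule flags values outside the Tukey fences", {
  expect_false(any(boxplot_outliers(1:10)))
  x <- c(1, 2, 2, 3, 3, 3, 4, 100)
  # oracle: type-7 quartiles
  qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  fence_hi <- qs[2] + 1.5 * (qs[2] - qs[1])
  expect_identical(boxplot_outliers(x), x > fence_hi | x < qs[1] -
                     1.5 * (qs[2] - qs[1]))
  expect_identical(which(boxplot_outliers(x)), 8L)
  expect_false(any(boxplot_outliers(rep(2, 6))))
})

test_that("outlier flags are computed within diagnostic group", {
  # a value moderate overall but extreme within its own group
  summ <- data.frame(
    subject_id = sprintf("s%02d", 1:16),
    warm_threshold = c(rep(1, 7), 3, rep(10, 8)),
    cool_threshold = 1, warm_gmd = 1, cool_gmd = 1)
  grp <- rep(c("A", "B"), each = 8)
  fl <- flag_outliers(summ, grp)
  expect_true(fl$outlier_warm[8])          # extreme within group A
  expect_false(any(fl$outlier_warm[9:16])) # uniform within group B
})
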