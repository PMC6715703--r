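test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_asd = 83, n_td = 59, seed = 1)
  s1 <- generate_cohort(cfg); s2 <- generate_cohort(cfg)
  expect_identical(s1, s2)
  t1 <- generate_trials(s1, cfg); t2 <- generate_trials(s2, cfg)
  expect_identical(t1, t2)
  m1 <- inject_missingness(s1, cfg$missing_rates, seed = 3)
  m2 <- inject_missingness(s1, cfg$missing_rates, seed = 3)
  expect_identical(m1, m2)
})

test_that("config validation names the offending field", {
  expect_error(synthetic_config(prop_child = 1.2), "prop_child")
  expect_error(synthetic_config(n_asd = 0), "n_asd")
  expect_error(synthetic_config(latent_log_sd = 0), "latent_log_sd")
  expect_error(synthetic_config(group_shift_delta = 1),
               "group_shift_delta")
  expect_error(synthetic_config(questionnaire_deltas = list(bogus = 0.5)),
               "unknown instrument")
  expect_error(synthetic_config(missing_rates = list(srs_t = 1.5)),
               "srs_t")
})

test_that("cohort structure matches the configuration", {
  cfg <- synthetic_config(n_asd = 60, n_td = 40, seed = 2)
  sub <- generate_cohort(cfg)
  expect_equal(nrow(sub), 100)
  expect_equal(sum(sub$diagnosis == "ASD"), 60)
  expect_false(anyDuplicated(sub$id) > 0)
  # severity score only for ASD rows
  expect_true(all(is.na(sub$ados_css[sub$diagnosis == "TD"])))
  expect_true(all(!is.na(sub$ados_css[sub$diagnosis == "ASD"])))
  # exactly one sensory questionnaire per subject, by age group
  adult <- sub$age_group == "adult"
  expect_true(all(!is.na(sub$aasp_low_registration[adult])))
  expect_true(all(is.na(sub$aasp_low_registration[!adult])))
  expect_true(all(!is.na(sub$sp_low_registration[!adult])))
  expect_true(all(is.na(sub$sp_low_registration[adult])))
  # age groups respect the 18-year boundary
  expect_true(all(sub$age[adult] >= 18))
  expect_true(all(sub$age[!adult] < 18))
})

test_that("null configuration produces near-zero group effects", {
  # average empirical deltas over several seeds so the Monte-Carlo
  # error (sd ~ 0.04 per cohort at 400/group) is well inside the band
  deltas <- lapply(thermolimits:::default_questionnaire_deltas(),
                   function(x) 0)
  d_q <- matrix(NA_real_, 4, 2, dimnames = list(NULL, c("viq", "srs_t")))
  d_thr <- numeric(4)
  for (i in 1:4) {
    cfg <- synthetic_config(n_asd = 400, n_td = 400,
                            group_shift_delta = 0, gmd_group_delta = 0,
                            piq_effect = 0, sex_effect = 0,
                            questionnaire_deltas = deltas, seed = 100 + i)
    sub <- generate_cohort(cfg)
    asd <- sub$diagnosis == "ASD"
    for (v in colnames(d_q))
      d_q[i, v] <- cliffs_delta(sub[[v]][asd], sub[[v]][!asd])$delta
    tr <- generate_trials(sub, cfg)
    summ <- summarize_thresholds(tr)
    summ <- merge(summ, sub[c("id", "diagnosis")], by.x = "subject_id",
                  by.y = "id")
    d_thr[i] <- cliffs_delta(summ$warm_threshold[summ$diagnosis == "ASD"],
                             summ$warm_threshold[summ$diagnosis ==
                                                   "TD"])$delta
  }
  expect_lt(max(abs(colMeans(d_q))), 0.05)
  expect_lt(abs(mean(d_thr)), 0.05)
})

test_that("questionnaire calibration recovers a configured delta", {
  cfg <- synthetic_config(n_asd = 500, n_td = 500,
                          questionnaire_deltas = list(srs_t = 0.97),
                          seed = 6)
  sub <- generate_cohort(cfg)
  asd <- sub$diagnosis == "ASD"
  d <- cliffs_delta(sub$srs_t[asd], sub$srs_t[!asd])$delta
  expect_gte(d, 0.95)
  expect_lte(d, 0.99)
})

test_that("trial table obeys the device and protocol invariants", {
  cfg <- synthetic_config(n_asd = 40, n_td = 30, seed = 7)
  sub <- generate_cohort(cfg)
  tr <- generate_trials(sub, cfg)
  expect_equal(nrow(tr), 70 * 20)
  counts <- table(tr$subject_id, tr$modality)
  expect_true(all(counts == 10))
  expect_true(all(tr$temperature >= 0 & tr$temperature <= 50))
  expect_true(all(tr$temperature[tr$modality == "warm"] >= 32))
  expect_true(all(tr$temperature[tr$modality == "cool"] <= 32))
  # heavy noise still cannot escape the bounds
  cfg2 <- synthetic_config(n_asd = 300, n_td = 300,
                           noise_log_level = log(25),
                           noise_coupling = 0, seed = 8)
  tr2 <- generate_trials(generate_cohort(cfg2), cfg2)
  expect_true(all(tr2$temperature >= 0 & tr2$temperature <= 50))
})

test_that("zero trial noise collapses each subject to identical trials", {
  cfg <- synthetic_config(n_asd = 10, n_td = 10, noise_coupling = 0,
                          noise_log_level = -Inf, noise_log_sd = 0,
                          seed = 9)
  sub <- generate_cohort(cfg)
  tr <- generate_trials(sub, cfg)
  summ <- summarize_thresholds(tr)
  expect_true(all(summ$warm_gmd == 0))
  expect_true(all(summ$cool_gmd == 0))
})

test_that("generate_trials demands complete required covariates", {
  cfg <- synthetic_config(n_asd = 5, n_td = 5, seed = 10)
  sub <- generate_cohort(cfg)
  sub$piq[2] <- NA
  expect_error(generate_trials(sub, cfg), "required covariates")
  expect_error(generate_trials(sub[0, ], cfg), "nonempty")
})

test_that("default coupling yields the expected threshold-GMD link", {
  cfg <- synthetic_config(n_asd = 150, n_td = 150, seed = 12)
  sub <- generate_cohort(cfg)
  tr <- generate_trials(sub, cfg)
  summ <- summarize_thresholds(tr)
  r <- spearman(summ$warm_threshold, summ$warm_gmd)
  expect_gte(r, 0.5)
  expect_lte(r, 0.85)
})

test_that("inject_missingness is MCAR at the configured rate", {
  tab <- data.frame(id = as.character(1:10000),
                    diagnosis = "TD", srs_t = rnorm(10000),
                    viq = rnorm(10000))
  same <- inject_missingness(tab, list(srs_t = 0), seed = 1)
  expect_identical(same, tab)
  all_gone <- inject_missingness(tab, list(viq = 1), seed = 1)
  expect_true(all(is.na(all_gone$viq)))
  part <- inject_missingness(tab, list(srs_t = 0.2), seed = 1)
  expect_equal(mean(is.na(part$srs_t)), 0.2, tolerance = 0.01)
  expect_error(inject_missingness(tab, list(diagnosis = 0.1)),
               "protected")
  expect_error(inject_missingness(tab, list(srs_t = -0.1)), "srs_t")
})

test_that("null cohorts give nominal delta-test rejection rates", {
  # the full generate -> summarize -> test chain under the null
  deltas <- lapply(thermolimits:::default_questionnaire_deltas(),
                   function(x) 0)
  rej <- vapply(1:2000, function(i) {
    cfg <- synthetic_config(n_asd = 20, n_td = 20,
                            group_shift_delta = 0, gmd_group_delta = 0,
                            piq_effect = 0, sex_effect = 0,
                            questionnaire_deltas = deltas,
                            seed = 20000 + i)
    sub <- generate_cohort(cfg)
    tr <- generate_trials(sub, cfg)
    summ <- summarize_thresholds(tr)
    asd <- sub$diagnosis[match(summ$subject_id, sub$id)] == "ASD"
    cliffs_delta(summ$warm_threshold[asd],
                 summ$warm_threshold[!asd])$p_two_sided < 0.05
  }, logical(1))
  # small-sample normal approximation: allow modest miscalibration
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("table and config round-trip through disk", {
  cfg <- synthetic_config(n_asd = 8, n_td = 7, seed = 13)
  sub <- generate_cohort(cfg)
  tr <- generate_trials(sub, cfg)
  td <- withr_like_tempdir()
  write_trial_table(tr, file.path(td, "trials.csv"))
  tr2 <- read_trial_table(file.path(td, "trials.csv"))
  expect_equal(tr2$temperature, tr$temperature, tolerance = 1e-12)
  write_subject_table(sub, file.path(td, "subjects.csv"))
  sub2 <- read_subject_table(file.path(td, "subjects.csv"))
  expect_equal(sub2$age, sub$age, tolerance = 1e-12)
  for (ext in c("yaml", "json")) {
    p <- file.path(td, paste0("cfg.", ext))
    write_config(cfg, p)
    cfg2 <- read_config(p)
    expect_equal(cfg2$latent_log_mean, cfg$latent_log_mean,
                 tolerance = 1e-12)
    expect_equal(cfg2$seed, cfg$seed)
    expect_equal(generate_cohort(cfg2), sub, tolerance = 1e-12)
  }
  bad <- tr; names(bad)[5] <- "temp"
  write.csv(bad, file.path(td, "bad.csv"), row.names = FALSE)
  expect_error(read_trial_table(file.path(td, "bad.csv")), "temperature")
})
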