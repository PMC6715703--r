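# Synthetic method-of-limits cohort generator.
#
# The generator emulates the distributional structure the analysis
# assumes: right-skewed (lognormal) subject thresholds, trial noise
# whose SD is coupled to the latent threshold on the log scale (which
# produces the observed rank correlation between threshold medians and
# trial-to-trial GMD and an outlier-prone tail), calibrated group
# separations expressed as Cliff's delta, and MCAR missingness on
# questionnaire/IQ covariates.

# Questionnaire/covariate roster: comparison-group normal baselines
# (means and SDs on the instruments' usual scales) and the age stratum
# each instrument applies to.
questionnaire_roster <- function() {
  data.frame(
    var = c("viq", "piq", "fsiq", "srs_t", "srs_item42",
            "aasp_low_registration", "aasp_seeking",
            "aasp_sensitivity", "aasp_avoiding",
            "sp_low_registration", "sp_seeking",
            "sp_sensitivity", "sp_avoiding"),
    td_mean = c(108, 109, 111, 42.5, 0.3,
                24.5, 45.4, 33.4, 32.2,
                70.1, 110.9, 88.7, 122.9),
    sd = c(15, 15, 14, 7, 0.8,
           5, 7, 5, 8,
           5, 11.5, 10, 12),
    stratum = c("all", "all", "all", "all", "all",
                "adult", "adult", "adult", "adult",
                "child", "child", "child", "child"),
    stringsAsFactors = FALSE)
}

default_questionnaire_deltas <- function() {
  list(viq = -0.347, piq = -0.122, fsiq = -0.285,
       srs_t = 0.971, srs_item42 = 0.729,
       aasp_low_registration = 0.869, aasp_seeking = -0.554,
       aasp_sensitivity = 0.748, aasp_avoiding = 0.733,
       sp_low_registration = -0.861, sp_seeking = -0.580,
       sp_sensitivity = -0.734, sp_avoiding = -0.817)
}

default_missing_rates <- function() {
  list(viq = 0.03, piq = 0.03, fsiq = 0.03,
       srs_t = 0.22, srs_item42 = 0.19, ados_css = 0.13,
       aasp_low_registration = 0.1, aasp_seeking = 0.1,
       aasp_sensitivity = 0.1, aasp_avoiding = 0.1,
       sp_low_registration = 0.12, sp_seeking = 0.12,
       sp_sensitivity = 0.12, sp_avoiding = 0.12)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the structure of the study cohort: 83 ASD and
#' 59 comparison subjects, about 60% children, lognormal latent warm
#' threshold-changes with median about 1.55 degC in the comparison
#' group and log-SD 0.6, full log-scale coupling between a subject's
#' latent threshold and their trial-noise SD, a dominance effect of
#' 0.17 on thresholds and 0.22 on trial-noise SDs, and questionnaire
#' group separations matching the reported instrument effect sizes.
#'
#' @param n_asd,n_td group sizes.
#' @param prop_child fraction of each group that is child/adolescent.
#' @param prop_male_asd,prop_male_td male fractions per group.
#' @param latent_log_mean,latent_log_sd lognormal parameters of the
#'   comparison-group latent warm threshold-change (degC, log scale).
#' @param cool_log_offset additive log-scale offset of cool vs warm
#'   latent changes.
#' @param noise_coupling coefficient linking log trial-noise SD to log
#'   latent threshold (1 = proportional noise).
#' @param noise_log_level,noise_log_sd mean and SD of the subject-level
#'   perturbation of log trial-noise SD (`-Inf` level forces
#'   deterministic trials).
#' @param group_shift_delta target Cliff's delta (ASD minus comparison)
#'   on thresholds.
#' @param gmd_group_delta target Cliff's delta on trial-noise SDs.
#' @param piq_effect log-scale slope of latent threshold on PIQ
#'   (per IQ point, centered at 105).
#' @param sex_effect additive male-female log-scale threshold shift.
#' @param questionnaire_deltas named list: instrument -> target Cliff's
#'   delta (ASD minus comparison).
#' @param missing_rates named list: variable -> MCAR missingness
#'   fraction, used by [inject_missingness()].
#' @param n_trials_per_block,n_blocks trial structure per modality.
#' @param seed integer seed; a fixed seed makes all generators
#'   bit-reproducible.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_asd = 83, n_td = 59,
                             prop_child = 86 / 142,
                             prop_male_asd = 62 / 83,
                             prop_male_td = 40 / 59,
                             latent_log_mean = log(1.55),
                             latent_log_sd = 0.6,
                             cool_log_offset = log(2.18 / 1.56),
                             noise_coupling = 1.0,
                             noise_log_level = log(0.45 / 1.7),
                             noise_log_sd = 0.6,
                             group_shift_delta = 0.17,
                             gmd_group_delta = 0.22,
                             piq_effect = -0.003,
                             sex_effect = 0.1,
                             questionnaire_deltas =
                               default_questionnaire_deltas(),
                             missing_rates = default_missing_rates(),
                             n_trials_per_block = 5,
                             n_blocks = 2,
                             seed = NULL) {
  cfg <- list(
    n_asd = check_count(n_asd, "n_asd"),
    n_td = check_count(n_td, "n_td"),
    prop_child = check_fraction(prop_child, "prop_child"),
    prop_male_asd = check_fraction(prop_male_asd, "prop_male_asd"),
    prop_male_td = check_fraction(prop_male_td, "prop_male_td"),
    latent_log_mean = latent_log_mean,
    latent_log_sd = latent_log_sd,
    cool_log_offset = cool_log_offset,
    noise_coupling = noise_coupling,
    noise_log_level = noise_log_level,
    noise_log_sd = noise_log_sd,
    group_shift_delta = group_shift_delta,
    gmd_group_delta = gmd_group_delta,
    piq_effect = piq_effect,
    sex_effect = sex_effect,
    questionnaire_deltas = questionnaire_deltas,
    missing_rates = missing_rates,
    n_trials_per_block = check_count(n_trials_per_block,
                                     "n_trials_per_block"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    seed = seed)
  if (!is.numeric(latent_log_sd) || latent_log_sd <= 0)
    stop_param("latent_log_sd", "must be > 0")
  if (!is.numeric(noise_log_sd) || noise_log_sd < 0)
    stop_param("noise_log_sd", "must be >= 0")
  for (nm in c("group_shift_delta", "gmd_group_delta"))
    if (abs(cfg[[nm]]) >= 1) stop_param(nm, "must lie inside (-1, 1)")
  if (!is.list(questionnaire_deltas) ||
      (length(questionnaire_deltas) &&
       is.null(names(questionnaire_deltas))))
    stop_param("questionnaire_deltas", "must be a named list")
  known <- questionnaire_roster()$var
  bad <- setdiff(names(questionnaire_deltas), known)
  if (length(bad))
    stop_param("questionnaire_deltas",
               paste("unknown instrument(s):", paste(bad, collapse = ", ")))
  if (any(abs(unlist(questionnaire_deltas)) >= 1))
    stop_param("questionnaire_deltas", "deltas must lie inside (-1, 1)")
  if (!is.list(missing_rates) ||
      (length(missing_rates) && is.null(names(missing_rates))))
    stop_param("missing_rates", "must be a named list")
  for (nm in names(missing_rates))
    check_fraction(missing_rates[[nm]], paste0("missing_rates$", nm))
  if (!is.null(seed)) {
    if (!is.numeric(seed) || seed != round(seed) || abs(seed) >= 2^31)
      stop_param("seed", "must be a 32-bit integer")
    cfg$seed <- as.integer(seed)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a subject-level cohort table
#'
#' Draws demographics and questionnaire scores for `n_asd + n_td`
#' subjects. Questionnaire group separations are calibrated so the
#' expected Cliff's delta equals the configured target, via the
#' normal-shift identity `shift = sqrt(2) * qnorm((delta + 1)/2) * sd`.
#' Sensory-profile scores are age-appropriate: the adult self-report
#' (AASP) quadrants for adults, the caregiver SP quadrants for
#' children; the calibration-severity score (`ados_css`) exists only
#' for ASD rows.
#'
#' @param config a [synthetic_config()].
#' @return data frame (one row per subject) with columns `id`,
#'   `diagnosis`, `age`, `age_group`, `sex`, the questionnaire roster,
#'   `ados_css`, `counterbalance`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_asd + config$n_td
    diagnosis <- rep(c("ASD", "TD"), c(config$n_asd, config$n_td))
    age_group <- ifelse(runif(n) < config$prop_child, "child", "adult")
    age <- ifelse(age_group == "child",
                  7 + 10.99 * rbeta(n, 1.5, 3),
                  pmin(18 + rgamma(n, shape = 2, scale = 5), 60))
    p_male <- ifelse(diagnosis == "ASD", config$prop_male_asd,
                     config$prop_male_td)
    sex <- ifelse(runif(n) < p_male, "M", "F")
    out <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      diagnosis = diagnosis, age = age, age_group = age_group,
      sex = sex, stringsAsFactors = FALSE)
    qs <- questionnaire_roster()
    for (i in seq_len(nrow(qs))) {
      v <- qs$var[i]
      delta <- config$questionnaire_deltas[[v]]
      if (is.null(delta)) delta <- 0
      shift <- delta_to_shift(delta, qs$sd[i])
      mu <- qs$td_mean[i] + ifelse(diagnosis == "ASD", shift, 0)
      val <- rnorm(n, mu, qs$sd[i])
      if (v == "srs_item42") val <- pmin(pmax(val, 0), 3)
      if (qs$stratum[i] == "adult") val[age_group != "adult"] <- NA
      if (qs$stratum[i] == "child") val[age_group != "child"] <- NA
      out[[v]] <- val
    }
    out$ados_css <- ifelse(
      diagnosis == "ASD",
      pmin(pmax(round(rnorm(n, 7.9, 1.8)), 1), 10), NA)
    out$counterbalance <- sample(c("warm_first", "cool_first"), n,
                                 replace = TRUE)
    out
  })
}

#' Generate a trial-level table for a cohort
#'
#' For each subject, modality, block, and trial: the subject's latent
#' threshold-change is lognormal with log-mean
#' `latent_log_mean + group shift + covariate effects + cool offset`
#' and log-SD `latent_log_sd` (one subject-level draw shared across
#' modalities); the trial-noise SD is
#' `exp(noise_coupling * log(mu) + nu)` with a subject-level
#' perturbation `nu`; recorded trial temperatures are
#' `32 +/- (mu + eps)` with `eps ~ N(0, sigma^2)`, the change clamped
#' to the physically reachable range (0 to 18 degC above baseline for
#' warm, 0 to 32 below for cool).
#'
#' The ASD shift of `nu` is chosen so the total dominance effect on
#' trial-noise SDs equals `gmd_group_delta` after accounting for the
#' part already induced through the threshold shift and the coupling.
#'
#' @param subjects cohort table from [generate_cohort()] (columns
#'   `id`, `diagnosis`, `sex`, `piq` required and complete).
#' @param config the same [synthetic_config()].
#' @return data frame with columns `subject_id`, `modality`, `block`,
#'   `trial`, `temperature`.
#' @export
generate_trials <- function(subjects, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.data.frame(subjects) || nrow(subjects) == 0)
    stop("`subjects` must be a nonempty data frame", call. = FALSE)
  need <- c("id", "diagnosis", "sex", "piq")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subject table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  incomplete <- !complete.cases(subjects[, need])
  if (any(incomplete))
    stop("subject(s) lacking required covariates: ",
         paste(utils::head(subjects$id[incomplete], 5), collapse = ", "),
         call. = FALSE)
  seed <- if (!is.null(config$seed)) config$seed + 1L else NULL
  with_seed(seed, {
    ns <- nrow(subjects)
    tpb <- config$n_trials_per_block
    nb <- config$n_blocks
    npm <- tpb * nb                       # trials per modality
    asd <- subjects$diagnosis == "ASD"
    grp_shift <- delta_to_shift(config$group_shift_delta,
                                config$latent_log_sd)
    z <- rnorm(ns)
    log_mu_warm <- config$latent_log_mean +
      ifelse(asd, grp_shift, 0) +
      config$piq_effect * (subjects$piq - 105) +
      config$sex_effect * (subjects$sex == "M") +
      config$latent_log_sd * z
    log_mu <- cbind(warm = log_mu_warm,
                    cool = log_mu_warm + config$cool_log_offset)
    # residual ASD shift on log trial-noise SD so the total dominance
    # effect on sigma matches gmd_group_delta
    s_tot <- sqrt((config$noise_coupling * config$latent_log_sd)^2 +
                    config$noise_log_sd^2)
    nu_shift <- if (s_tot > 0)
      delta_to_shift(config$gmd_group_delta, s_tot) -
        config$noise_coupling * grp_shift else 0
    nu <- config$noise_log_level + ifelse(asd, nu_shift, 0) +
      if (config$noise_log_sd > 0) rnorm(ns, 0, config$noise_log_sd) else 0
    rows <- vector("list", 2L)
    for (m in 1:2) {
      mod <- c("warm", "cool")[m]
      mu <- exp(log_mu[, mod])
      sigma <- exp(config$noise_coupling * log_mu[, mod] + nu)
      eps <- matrix(rnorm(ns * npm, 0, rep(sigma, each = npm)),
                    nrow = npm)
      ch <- sweep(eps, 2, mu, "+")
      cap <- if (mod == "warm") 18 else 32
      ch <- pmin(pmax(ch, 0), cap)
      temp <- if (mod == "warm") 32 + ch else 32 - ch
      rows[[m]] <- data.frame(
        subject_id = rep(subjects$id, each = npm),
        modality = mod,
        block = rep(rep(seq_len(nb), each = tpb), times = ns),
        trial = rep(rep(seq_len(tpb), times = nb), times = ns),
        temperature = as.vector(temp),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$subject_id, out$modality, out$block, out$trial), ]
    rownames(out) <- NULL
    out
  })
}

#' Inject MCAR missingness into a table
#'
#' Sets each named variable to `NA` independently, completely at
#' random, at its configured rate. Identifier, diagnosis, and
#' trial-structure columns are protected and may not be degraded.
#'
#' @param table data frame.
#' @param missing_rates named list: column -> rate in \[0, 1\].
#' @param seed optional integer seed (RNG state restored).
#' @return the table with missingness injected.
#' @export
inject_missingness <- function(table, missing_rates, seed = NULL) {
  stopifnot(is.data.frame(table))
  protected <- c("id", "subject_id", "diagnosis", "modality", "block",
                 "trial", "temperature")
  if (!is.list(missing_rates) ||
      (length(missing_rates) && is.null(names(missing_rates))))
    stop_param("missing_rates", "must be a named list")
  for (nm in names(missing_rates)) {
    if (nm %in% protected)
      stop_param(nm, "is a protected variable and may not be set missing")
    check_fraction(missing_rates[[nm]], nm)
  }
  with_seed(seed, {
    for (nm in names(missing_rates)) {
      if (!nm %in% names(table)) next
      r <- missing_rates[[nm]]
      if (r > 0)
        table[[nm]][runif(nrow(table)) < r] <- NA
    }
    table
  })
}

#' @rdname table_io
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write trial and subject tables as CSV
#'
#' Plain UTF-8 CSV with a header row and `.` decimal separator. Readers
#' validate the schema and basic invariants and fail with the offending
#' column named.
#'
#' @param trials,subjects data frames to write.
#' @param path file path.
#' @return the table (readers) or the path, invisibly (writers).
#' @name table_io
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "modality", "block", "trial", "temperature")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(tab$modality %in% c("warm", "cool")))
    stop("column `modality` must be \"warm\" or \"cool\"", call. = FALSE)
  if (!is.numeric(tab$temperature) ||
      any(!is.finite(tab$temperature)) ||
      any(tab$temperature < 0 | tab$temperature > 50))
    stop("column `temperature` must be numeric within [0, 50]",
         call. = FALSE)
  tab
}

#' @rdname table_io
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "diagnosis", "age", "age_group", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("subject table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("column `id` contains duplicates", call. = FALSE)
  tab
}

#' Read/write a generator or analysis configuration
#'
#' Serialized as YAML (`.yml`/`.yaml`) or JSON (`.json`), with the seed
#' stored explicitly.
#'
#' @param config a `synthetic_config` (or plain named list).
#' @param path destination/source path; format chosen by extension.
#' @return the configuration (readers) or the path, invisibly.
#' @name config_io
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame =
                          FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- x[intersect(names(x), names(formals(synthetic_config)))]
  do.call(synthetic_config, args)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d ASD / %d TD, %d blocks x %d trials, seed %s\n",
    x$n_asd, x$n_td, x$n_blocks, x$n_trials_per_block,
    if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
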