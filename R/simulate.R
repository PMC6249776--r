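## Synthetic two-cohort case-control glycomics datasets.
##
## Peak compositions are logistic-normal: log abundances are drawn around
## a fixed baseline profile, status/smoking effects are injected as
## log-scale mean shifts calibrated so the realized trait difference lands
## near the requested effect in SD units, batch artifacts are added on the
## log scale, and vectors are closed to 100%. Everything is driven by one
## integer seed; the injected truth is returned alongside the data.

#' Fixed baseline peak profile for a panel
#'
#' A smooth synthetic mean composition (percent of total area) with a few
#' dominant peak clusters, qualitatively like real HILIC profiles. It is a
#' stand-in, not an estimate of any real cohort.
#'
#' @param panel `"plasma"` or `"igg"`
#' @return named numeric vector of percentages summing to 100
#' @export
glycan_baseline_profile <- function(panel = c("plasma", "igg")) {
  panel <- match.arg(panel)
  if (panel == "plasma") {
    k <- 1:39
    w <- 1.2 * exp(-((k - 6) / 3)^2) + 3.0 * exp(-((k - 14) / 2.5)^2) +
      1.5 * exp(-((k - 21) / 3)^2) + 0.8 * exp(-((k - 28) / 3)^2) +
      0.5 * exp(-((k - 35) / 3)^2) + 0.15
  } else {
    k <- 1:24
    w <- 2.5 * exp(-((k - 4) / 2)^2) + 2.0 * exp(-((k - 9) / 2.5)^2) +
      1.2 * exp(-((k - 14) / 2.5)^2) + 0.8 * exp(-((k - 18) / 2.5)^2) +
      0.5 * exp(-((k - 22) / 2)^2) + 0.12
  }
  p <- 100 * w / sum(w)
  setNames(p, peak_names(panel))
}

#' Default injected case-control effects (SD units of the derived trait)
#'
#' Directions follow the replicated COPD findings: lower low-branched and
#' monogalactosylated glycans, higher high-branched, tetragalactosylated,
#' tri-/tetrasialylated and antennary-fucosylated species in cases; for
#' IgG, lower monogalactosylation and more bisecting GlcNAc. Magnitudes
#' are moderate placeholders (0.25-0.4 SD) -- the source cohorts' effect
#' sizes are not public.
#'
#' @param panel `"plasma"` or `"igg"`
#' @return named numeric vector (trait -> effect in SD units)
#' @export
default_effect_map <- function(panel = c("plasma", "igg")) {
  panel <- match.arg(panel)
  if (panel == "plasma") {
    c(LB = -0.3, G1 = -0.4, HB = 0.3, G4 = 0.4, S3 = 0.3, S4 = 0.4,
      AntF = 0.3)
  } else {
    c(G1 = -0.4, Bisecting = 0.25)
  }
}

#' Default smoking effects on glycans (SD units, current smokers)
#'
#' Active smoking shifts the glycome towards more complex structures
#' (higher branching, galactosylation, sialylation, antennary fucose;
#' lower core fucose and simple structures); ex-smokers show the same
#' pattern attenuated. Magnitudes are placeholders.
#'
#' @param panel `"plasma"` or `"igg"`
#' @return named numeric vector (trait -> effect in SD units)
#' @export
default_smoking_effect_map <- function(panel = c("plasma", "igg")) {
  panel <- match.arg(panel)
  if (panel == "plasma") {
    c(LB = -0.4, CoreF = -0.3, G0 = -0.3, G1 = -0.3, S0 = -0.3,
      HB = 0.4, G2 = 0.3, G4 = 0.3, S2 = 0.25, S3 = 0.3, S4 = 0.3,
      AntF = 0.3)
  } else {
    c(Bisecting = 0.4, CoreF = -0.3)
  }
}

## Table-2-style covariate distributions per cohort and group. The printed
## medians/frequencies anchor the distributions; spreads are plausible
## placeholders.
default_covariate_model <- function() {
  list(
    list( # cohort 1 (discovery)
      control = list(age_mean = 62.5, age_sd = 6.5, male_frac = 0.52,
                     smoking = c(never = 0.51, current = 0.49, ex = 0.00),
                     fvc = 3.35, fev1 = 2.60, ratio = 80.6,
                     hscrp = 2.02, fibrinogen = 3.50),
      case = list(age_mean = 65, age_sd = 8, male_frac = 0.63,
                  smoking = c(never = 0.07, current = 0.27, ex = 0.66),
                  gold = c(`1` = 0.00, `2` = 0.35, `3` = 0.36, `4` = 0.29),
                  abcd = c(A = 0.48, B = 0.23, C = 0.05, D = 0.24),
                  exac = c(`0` = 0.28, `1` = 0.43, `2plus` = 0.29),
                  fvc = 2.28, fev1 = 1.08, ratio = 48.2,
                  hscrp = 2.49, fibrinogen = 3.80)
    ),
    list( # cohort 2 (replication)
      control = list(age_mean = 51, age_sd = 8, male_frac = 0.35,
                     smoking = c(never = 0.44, current = 0.38, ex = 0.18),
                     fvc = 3.77, fev1 = 2.96, ratio = 79.1,
                     hscrp = 1.10, fibrinogen = 3.20),
      case = list(age_mean = 65, age_sd = 8, male_frac = 0.67,
                  smoking = c(never = 0.08, current = 0.70, ex = 0.22),
                  gold = c(`1` = 0.18, `2` = 0.38, `3` = 0.30, `4` = 0.14),
                  abcd = c(A = 0.21, B = 0.34, C = 0.08, D = 0.37),
                  exac = c(`0` = 0.51, `1` = 0.34, `2plus` = 0.15),
                  fvc = 3.33, fev1 = 1.49, ratio = 50.6,
                  hscrp = 2.20, fibrinogen = 3.80)
    )
  )
}

#' Configuration for the two-cohort simulator
#'
#' Defaults reproduce the study design being emulated: a discovery cohort
#' of 137 cases / 95 controls and a replication cohort of 61 cases / 148
#' controls, compositional peak vectors, log-scale batch artifacts,
#' case-control and smoking effects in the replicated directions, and
#' cases that are older, more often male and more often (ex-)smokers.
#'
#' @param n_cases_per_cohort integer vector of case counts per cohort
#' @param n_controls_per_cohort integer vector of control counts
#' @param panel `"plasma"` or `"igg"`
#' @param n_batches_per_cohort batches per cohort (subjects assigned at
#'   random, sizes balanced)
#' @param batch_shift_sd SD of the additive per-batch/peak log-scale shift
#' @param batch_scale_sd SD of the log multiplicative batch effect
#' @param effect_map named numeric: trait or peak name -> case-control
#'   effect in SD units (empty vector for a null simulation)
#' @param smoking_effect_map named numeric: trait or peak -> effect of
#'   current smoking in SD units (ex-smokers attenuated)
#' @param ex_smoker_attenuation multiplier for ex-smokers' smoking effect
#' @param gold_dose named numeric, per-GOLD-stage multiplier of the case
#'   effect (monotone by default so severity grades the glycome shift);
#'   the mean dose over simulated cases is normalised out so `effect_map`
#'   stays calibrated to the average case
#' @param covariate_model list of per-cohort covariate distributions; see
#'   `default_covariate_model` in the package source
#' @param dispersion SD of the per-peak log-abundance noise
#'   (logistic-normal scale)
#' @param seed master integer seed; fully determines the output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_cases_per_cohort = c(137, 61),
                       n_controls_per_cohort = c(95, 148),
                       panel = c("plasma", "igg"),
                       n_batches_per_cohort = 3,
                       batch_shift_sd = 0.2,
                       batch_scale_sd = 0.05,
                       effect_map = default_effect_map(panel),
                       smoking_effect_map = default_smoking_effect_map(panel),
                       ex_smoker_attenuation = 0.5,
                       gold_dose = c(`1` = 0.7, `2` = 0.9, `3` = 1.1,
                                     `4` = 1.3),
                       covariate_model = default_covariate_model(),
                       dispersion = 0.25,
                       seed = 1L) {
  panel <- match.arg(panel)
  cfg <- list(n_cases_per_cohort = as.integer(n_cases_per_cohort),
              n_controls_per_cohort = as.integer(n_controls_per_cohort),
              panel = panel,
              n_batches_per_cohort = as.integer(n_batches_per_cohort),
              batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd,
              effect_map = effect_map,
              smoking_effect_map = smoking_effect_map,
              ex_smoker_attenuation = ex_smoker_attenuation,
              gold_dose = gold_dose,
              covariate_model = covariate_model,
              dispersion = dispersion,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  k <- length(cfg$n_cases_per_cohort)
  assert_that(k >= 1 && length(cfg$n_controls_per_cohort) == k,
              "case and control counts must cover the same cohorts")
  assert_that(all(cfg$n_cases_per_cohort >= 2) &&
              all(cfg$n_controls_per_cohort >= 2),
              "need at least 2 cases and 2 controls per cohort")
  assert_that(cfg$n_batches_per_cohort >= 1, "need at least one batch")
  per_batch <- (cfg$n_cases_per_cohort + cfg$n_controls_per_cohort) %/%
    cfg$n_batches_per_cohort
  assert_that(all(per_batch >= 2),
              "batch sizes would fall below 2 subjects")
  assert_that(length(cfg$covariate_model) >= k,
              "covariate_model must describe every cohort")
  valid <- c(peak_names(cfg$panel),
             names(load_trait_definitions(cfg$panel)))
  for (m in list(cfg$effect_map, cfg$smoking_effect_map)) {
    if (length(m)) {
      bad <- setdiff(names(m), valid)
      assert_that(length(bad) == 0,
                  "effect map keys not in panel '%s': %s", cfg$panel,
                  paste(bad, collapse = ", "))
    }
  }
  assert_that(cfg$dispersion > 0, "dispersion must be positive")
  invisible(cfg)
}

## Direction vector in peak space for a trait or single peak.
effect_direction <- function(key, panel, defs) {
  pk <- peak_names(panel)
  d <- setNames(numeric(length(pk)), pk)
  if (key %in% pk) {
    d[key] <- 1
  } else {
    co <- defs[[key]]$coefficients
    d[names(co)] <- co
  }
  d
}

## Calibrate the log-scale shift so the realized difference of the target
## quantity (after closure) is `target` control-SDs. Pilot Monte-Carlo with
## one Newton refinement; exact SD calibration is approximate by design.
calibrate_shift <- function(key, target, mu, dispersion, defs, panel,
                            n_pilot = 400) {
  d <- effect_direction(key, panel, defs)
  E <- matrix(rnorm(n_pilot * length(mu), 0, dispersion), n_pilot)
  value_at <- function(delta) {
    x <- exp(sweep(E, 2, mu + delta * d, "+"))
    pct <- 100 * x / rowSums(x)
    colnames(pct) <- names(mu)
    if (key %in% names(mu)) pct[, key] else
      drop(compute_derived_traits(pct, defs[key]))
  }
  v0 <- value_at(0)
  sd0 <- sd(v0)
  want <- target * sd0
  delta <- 0.1 * sign(target)
  slope <- (mean(value_at(delta)) - mean(v0)) / delta
  delta <- want / slope
  got <- mean(value_at(delta)) - mean(v0)
  if (abs(got) > 1e-12) delta <- delta * want / got
  delta * d
}

draw_multinomial <- function(n, probs) {
  probs <- probs / sum(probs)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

## exact male count (rounded from the configured fraction), random order
draw_sex <- function(n, male_frac) {
  n_m <- round(male_frac * n)
  sample(c(rep("M", n_m), rep("F", n - n_m)))
}

draw_group_phenotypes <- function(n, pars, status, cohort) {
  age <- pmin(pmax(round(rnorm(n, pars$age_mean, pars$age_sd)), 40), 80)
  sex <- draw_sex(n, pars$male_frac)
  smoking <- draw_multinomial(n, pars$smoking)
  pack_years <- ifelse(smoking == "never", 0,
                       10 + rgamma(n, shape = 2, scale = 10))
  gold <- if (status == 1) draw_multinomial(n, pars$gold) else
    rep(NA_character_, n)
  abcd <- if (status == 1) draw_multinomial(n, pars$abcd) else
    rep(NA_character_, n)
  exac <- if (status == 1) draw_multinomial(n, pars$exac) else
    rep(NA_character_, n)
  fvc <- pmax(rnorm(n, pars$fvc, 0.55), 0.5)
  fev1 <- pmax(rnorm(n, pars$fev1, if (status == 1) 0.4 else 0.5), 0.3)
  ratio <- pmin(pmax(rnorm(n, pars$ratio, 6), 20), 95)
  data.frame(cohort = cohort, status = status, age = age, sex = sex,
             smoking = smoking, pack_years = round(pack_years, 1),
             gold = gold, abcd = abcd, exacerbations = exac,
             fev1 = round(fev1, 2), fvc = round(fvc, 2),
             fev1_fvc = round(ratio, 1),
             hscrp = round(rlnorm(n, log(pars$hscrp), 0.45), 2),
             fibrinogen = round(rlnorm(n, log(pars$fibrinogen), 0.12), 2),
             stringsAsFactors = FALSE)
}

#' Apply synthetic batch effects to a log-abundance matrix
#'
#' Per batch and peak, adds an additive shift drawn from
#' `N(0, shift_sd^2)` and scales values centred at the per-peak overall
#' mean by `exp(N(0, scale_sd^2))`. The drawn parameters are attached as
#' attribute `truth` (`shift` and `log_scale`, batches x peaks).
#'
#' @param log_matrix numeric matrix, subjects x peaks, log scale
#' @param batches per-subject batch labels, every batch with >= 2 subjects
#' @param shift_sd SD of the additive shift (0 disables)
#' @param scale_sd SD of the log multiplicative effect (0 disables)
#' @param seed integer seed for the draws
#' @return the perturbed matrix with attribute `truth`
#' @export
apply_batch_effects <- function(log_matrix, batches, shift_sd, scale_sd,
                                seed = 1L) {
  assert_that(length(batches) == nrow(log_matrix),
              "batch labels must match rows")
  sizes <- table(batches)
  assert_that(all(sizes >= 2), "every batch needs at least 2 subjects")
  bl <- names(sizes)
  p <- ncol(log_matrix)
  withr::with_seed(seed, {
    shift <- matrix(rnorm(length(bl) * p, 0, shift_sd), length(bl),
                    dimnames = list(bl, colnames(log_matrix)))
    lsc <- matrix(rnorm(length(bl) * p, 0, scale_sd), length(bl),
                  dimnames = list(bl, colnames(log_matrix)))
  })
  if (shift_sd == 0) shift[] <- 0
  if (scale_sd == 0) lsc[] <- 0
  ctr <- colMeans(log_matrix)
  out <- log_matrix
  for (b in bl) {
    i <- which(batches == b)
    cen <- sweep(out[i, , drop = FALSE], 2, ctr, "-")
    out[i, ] <- sweep(sweep(cen, 2, exp(lsc[b, ]), "*"), 2,
                      ctr + shift[b, ], "+")
  }
  attr(out, "truth") <- list(shift = shift, log_scale = lsc)
  out
}

#' Simulate a two-cohort case-control glycomics dataset
#'
#' Draws covariates per cohort and group, injects calibrated case-control
#' and smoking effects on the log abundances of the peaks that make up
#' each targeted trait, applies per-cohort batch artifacts on the log
#' scale and closes each peak vector to 100%. Case effects are graded by
#' GOLD stage through `gold_dose` (normalised so the average case carries
#' the nominal effect).
#'
#' @param config a [sim_config()]
#' @return a `glyco_sim` list with elements `peaks` (data frame:
#'   `subject_id`, `cohort`, `batch`, peak columns), `phenotypes`
#'   (data frame of clinical covariates) and `truth` (injected effects,
#'   calibrated log shifts and batch parameters)
#' @export
simulate_cohorts <- function(config) {
  validate_sim_config(config)
  panel <- config$panel
  pk <- peak_names(panel)
  defs <- load_trait_definitions(panel)
  mu <- log(glycan_baseline_profile(panel))

  withr::with_seed(config$seed, {
    shift_status <- setNames(numeric(length(pk)), pk)
    for (key in names(config$effect_map)) {
      shift_status <- shift_status +
        calibrate_shift(key, config$effect_map[[key]], mu,
                        config$dispersion, defs, panel)
    }
    shift_smoke <- setNames(numeric(length(pk)), pk)
    for (key in names(config$smoking_effect_map)) {
      shift_smoke <- shift_smoke +
        calibrate_shift(key, config$smoking_effect_map[[key]], mu,
                        config$dispersion, defs, panel)
    }

    phen_list <- list(); peak_list <- list(); batch_truth <- list()
    for (ci in seq_along(config$n_cases_per_cohort)) {
      cm <- config$covariate_model[[ci]]
      n1 <- config$n_cases_per_cohort[ci]
      n0 <- config$n_controls_per_cohort[ci]
      ph <- rbind(
        draw_group_phenotypes(n0, cm$control, 0L, ci),
        draw_group_phenotypes(n1, cm$case, 1L, ci))
      n <- n0 + n1

      dose <- rep(0, n)
      is_case <- ph$status == 1
      dose[is_case] <- config$gold_dose[ph$gold[is_case]]
      dose[is.na(dose)] <- 1  # cases without a stage carry the nominal effect
      if (any(is_case) && mean(dose[is_case]) > 0) {
        dose <- dose / mean(dose[is_case])
      }
      smoke_dose <- c(never = 0, current = 1,
                      ex = config$ex_smoker_attenuation)[ph$smoking]

      logx <- matrix(rnorm(n * length(pk), 0, config$dispersion), n,
                     dimnames = list(NULL, pk))
      logx <- sweep(logx, 2, mu, "+") +
        outer(dose, shift_status) + outer(smoke_dose, shift_smoke)

      batch <- sample(rep_len(sprintf("c%d_b%d", ci,
                                      seq_len(config$n_batches_per_cohort)),
                              n))
      logx <- apply_batch_effects(logx, batch, config$batch_shift_sd,
                                  config$batch_scale_sd,
                                  seed = derive_seed(config$seed, ci))
      batch_truth[[ci]] <- attr(logx, "truth")
      attr(logx, "truth") <- NULL

      x <- exp(logx)
      pct <- 100 * x / rowSums(x)
      ids <- sprintf("S%d_%04d", ci, seq_len(n))
      peak_list[[ci]] <- data.frame(subject_id = ids, cohort = ci,
                                    batch = batch, pct,
                                    stringsAsFactors = FALSE)
      ph <- cbind(subject_id = ids, ph)
      phen_list[[ci]] <- ph
    }
  })

  structure(list(
    peaks = do.call(rbind, peak_list),
    phenotypes = do.call(rbind, phen_list),
    truth = list(panel = panel,
                 effect_map = config$effect_map,
                 smoking_effect_map = config$smoking_effect_map,
                 log_shift_status = shift_status,
                 log_shift_smoking = shift_smoke,
                 gold_dose = config$gold_dose,
                 batch = batch_truth,
                 seed = config$seed)),
    class = "glyco_sim")
}

#' @export
print.glyco_sim <- function(x, ...) {
  cat(sprintf(
    "<glyco_sim> %s panel: %d subjects in %d cohorts (%d cases)\n",
    x$truth$panel, nrow(x$peaks), length(unique(x$peaks$cohort)),
    sum(x$phenotypes$status)))
  invisible(x)
}

#' Write a simulated dataset to CSV/JSON files
#'
#' Writes `peaks.csv`, `phenotypes.csv` and `truth.json` into `dir`.
#'
#' @param sim a `glyco_sim` from [simulate_cohorts()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("peaks.csv", "phenotypes.csv", "truth.json"))
  write.csv(sim$peaks, paths[1], row.names = FALSE)
  write.csv(sim$phenotypes, paths[2], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[3], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
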