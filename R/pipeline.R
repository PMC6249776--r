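## End-to-end orchestration: simulate (or load) -> preprocess per cohort
## -> derived traits -> per-cohort association -> random-effects meta ->
## FDR. Cohorts are processed independently up to the meta-analysis
## stage, mirroring the per-cohort analysis design.

#' Run the full association pipeline on a two-cohort dataset
#'
#' For each cohort separately: total-area normalisation, log transform,
#' ComBat batch correction (batches within cohort), back-transformation,
#' derived-trait computation, and case-control (and optional clinical
#' feature) association models. Per-cohort results are pooled by
#' random-effects meta-analysis with BH FDR control per reporting family.
#'
#' @param peaks data frame with `subject_id`, `cohort`, `batch` and peak
#'   columns (percent or raw areas; rows re-normalised either way)
#' @param phenotypes phenotype data frame aligned by `subject_id`
#' @param panel `"plasma"` or `"igg"`
#' @param features named list describing additional feature analyses,
#'   e.g. `list(gold = "categorical", fev1_fvc = "continuous")`; referent
#'   for case-only categorical features is the control group, for
#'   `smoking` the never-smokers
#' @param include_peaks also test the directly measured peaks (not just
#'   derived traits)
#' @param floor flooring threshold for [log_transform()]
#' @param protect_status include case/control status as a protected
#'   covariate in the batch-correction design
#' @param method tau^2 estimator for the meta-analysis
#' @param family_policy BH family policy, see [run_meta_analysis()]
#' @return list with `meta` (pooled results), `assoc` (per-cohort rows),
#'   `traits` (per-cohort trait matrices), `adjusted` (per-cohort
#'   percent-adjusted peak matrices) and `descriptives`
#' @export
run_pipeline <- function(peaks, phenotypes, panel = c("plasma", "igg"),
                         features = list(),
                         include_peaks = TRUE, floor = 1e-4,
                         protect_status = FALSE, method = "REML",
                         family_policy = "per_family") {
  panel <- match.arg(panel)
  pk <- peak_names(panel)
  assert_that(all(pk %in% names(peaks)),
              "peak table must contain columns %s...", pk[1])
  assert_that(all(c("subject_id", "cohort", "batch") %in% names(peaks)),
              "peak table needs subject_id, cohort, batch")
  phenotypes <- phenotypes[match(peaks$subject_id,
                                 phenotypes$subject_id), , drop = FALSE]
  assert_that(!anyNA(phenotypes$subject_id),
              "phenotypes missing for some subjects")

  defs <- load_trait_definitions(panel)
  cohorts <- sort(unique(peaks$cohort))
  assoc <- list(); traits_out <- list(); adj_out <- list(); descr <- list()
  for (co in cohorts) {
    i <- peaks$cohort == co
    ph <- phenotypes[i, , drop = FALSE]
    raw <- peaks[i, pk, drop = FALSE]
    covariates <- if (protect_status) cbind(status = ph$status) else NULL
    adj <- preprocess_peaks(raw, batch = peaks$batch[i], floor = floor,
                            covariates = covariates)
    tr <- compute_derived_traits(adj, defs)
    traits_out[[as.character(co)]] <- tr
    adj_out[[as.character(co)]] <- adj
    descr[[as.character(co)]] <- describe_cohorts(ph)

    vars <- list(list(g = as.data.frame(tr), type = "derived"))
    if (include_peaks) {
      vars <- c(vars, list(list(g = as.data.frame(unclass_matrix(adj)),
                                type = "peak")))
    }
    for (v in vars) {
      assoc[[length(assoc) + 1]] <-
        associate_case_control(v$g, ph, cohort = co, var_type = v$type,
                               panel = panel)
      for (f in names(features)) {
        ref <- if (f == "smoking") "never" else "control"
        assoc[[length(assoc) + 1]] <-
          associate_feature(v$g, ph, f, kind = features[[f]],
                            cohort = co, referent = ref,
                            var_type = v$type, panel = panel)
      }
    }
  }
  assoc <- do.call(rbind, assoc)
  meta <- run_meta_analysis(assoc, method = method,
                            family_policy = family_policy)
  list(meta = meta, assoc = assoc, traits = traits_out,
       adjusted = adj_out, descriptives = descr)
}

#' Simulate a dataset and run the full pipeline on it
#'
#' Convenience wrapper for calibration studies:
#' [simulate_cohorts()] followed by [run_pipeline()].
#'
#' @param config a [sim_config()]
#' @param ... passed to [run_pipeline()]
#' @return the [run_pipeline()] result with the simulation attached as
#'   `sim`
#' @export
simulate_and_run <- function(config, ...) {
  sim <- simulate_cohorts(config)
  res <- run_pipeline(sim$peaks, sim$phenotypes, panel = config$panel,
                      ...)
  res$sim <- sim
  res
}

#' Assemble reporting tables from meta-analysis results
#'
#' Produces, per reporting family, the table of significant rows
#' (adjusted p below the threshold) alongside the full table, plus the
#' per-cohort descriptive tables.
#'
#' @param meta pooled results from [run_meta_analysis()]
#' @param descriptives optional list of per-cohort descriptive tables
#' @param alpha significance threshold on the adjusted p-value
#' @return list with `full`, `significant` (named by family) and
#'   `descriptives`
#' @export
build_report <- function(meta, descriptives = NULL, alpha = 0.05) {
  sig <- meta[!is.na(meta$p_adj) & meta$p_adj < alpha, , drop = FALSE]
  list(full = meta,
       significant = split(sig, sig$family),
       descriptives = descriptives)
}
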