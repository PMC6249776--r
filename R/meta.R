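## Inverse-variance random-effects meta-analysis across cohorts and
## Benjamini-Hochberg FDR control within reporting families. With two
## cohorts the between-cohort variance tau^2 is weakly identified; REML
## (via metafor) is the default with a DerSimonian-Laird fallback on
## non-convergence, and the estimator actually used is tagged per row.

#' Random-effects meta-analysis of per-cohort effects
#'
#' Pools per-cohort estimates with inverse-variance weights
#' `w_i = 1 / (se_i^2 + tau^2)`. `tau^2` is estimated by REML (iterative,
#' floored at zero; the metafor implementation) or by the
#' DerSimonian-Laird closed form. The pooled z and two-sided normal
#' p-value come from `beta / se`.
#'
#' @param betas numeric vector of per-cohort effects (k >= 2)
#' @param ses positive per-cohort standard errors
#' @param method `"REML"` (default) or `"DL"`
#' @return list with `beta`, `se`, `tau2`, `z`, `p`, `k`, `method`
#' @export
#' @examples
#' meta_random_effects(c(0, 2), c(0.5, 0.5), method = "DL")
#' # pooled 1.0, tau2 = 1.75, se = 1.0
meta_random_effects <- function(betas, ses, method = c("REML", "DL")) {
  method <- match.arg(method)
  assert_that(length(betas) >= 2, "need at least 2 cohorts")
  assert_that(length(ses) == length(betas) && all(ses > 0),
              "standard errors must be positive and match betas")
  used <- method
  fit <- NULL
  if (method == "REML") {
    fit <- tryCatch(
      suppressWarnings(metafor::rma.uni(yi = betas, sei = ses,
                                        method = "REML",
                                        control = list(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) used <- "DL"
  }
  if (is.null(fit)) {
    fit <- metafor::rma.uni(yi = betas, sei = ses, method = "DL")
  }
  list(beta = as.numeric(fit$beta), se = fit$se, tau2 = fit$tau2,
       z = as.numeric(fit$zval), p = as.numeric(fit$pval),
       k = length(betas), method = used)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust`, method `"BH"`), with input
#' validation restricting p-values to (0, 1].
#'
#' @param p vector of raw p-values in (0, 1]
#' @return adjusted p-values in the original order
#' @export
bh_adjust <- function(p) {
  assert_that(length(p) >= 1 && all(is.finite(p)) && all(p > 0) &&
              all(p <= 1), "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Meta-analyse per-cohort association tables and control FDR
#'
#' Groups association rows by (variable, model, feature, level), excludes
#' flagged per-cohort fits (e.g. separation), pools every group present
#' in at least two cohorts with [meta_random_effects()], and applies
#' [bh_adjust()] within each reporting family: panel x variable type
#' (directly measured peak vs derived trait) x analysis feature, or one
#' global family if `family_policy = "global"`. Groups observed in a
#' single cohort are emitted with `k = 1` and no adjusted p.
#'
#' @param assoc data frame of per-cohort rows as produced by
#'   [associate_case_control()] / [associate_feature()] (must include a
#'   `cohort` column)
#' @param method tau^2 estimator passed to [meta_random_effects()]
#' @param family_policy `"per_family"` (default) or `"global"`
#' @param alpha significance threshold on the adjusted p-value
#' @return data frame with one row per (variable, feature, level):
#'   pooled `beta`, `se`, `tau2`, `z`, `p`, `p_adj`, `k`, `family`,
#'   `significant`, `method`
#' @export
run_meta_analysis <- function(assoc, method = "REML",
                              family_policy = c("per_family", "global"),
                              alpha = 0.05) {
  family_policy <- match.arg(family_policy)
  need <- c("variable", "var_type", "panel", "cohort", "model",
            "feature", "level", "beta", "se", "p", "flag")
  assert_that(all(need %in% names(assoc)),
              "association table is missing columns: %s",
              paste(setdiff(need, names(assoc)), collapse = ", "))
  ok <- assoc$flag == "" & is.finite(assoc$beta) & is.finite(assoc$se)
  assoc <- assoc[ok, , drop = FALSE]
  key <- interaction(assoc$variable, assoc$model, assoc$feature,
                     ifelse(is.na(assoc$level), "", assoc$level),
                     drop = TRUE)
  out <- lapply(split(assoc, key), function(d) {
    base <- d[1, c("variable", "var_type", "panel", "model", "feature",
                   "level")]
    if (nrow(d) >= 2) {
      m <- meta_random_effects(d$beta, d$se, method = method)
      cbind(base, data.frame(beta = m$beta, se = m$se, tau2 = m$tau2,
                             z = m$z, p = m$p, k = m$k,
                             method = m$method,
                             stringsAsFactors = FALSE))
    } else {
      cbind(base, data.frame(beta = d$beta, se = d$se, tau2 = NA_real_,
                             z = d$beta / d$se, p = d$p, k = 1L,
                             method = "single-cohort",
                             stringsAsFactors = FALSE))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$family <- if (family_policy == "global") "all" else
    paste(res$panel, res$var_type, res$feature, sep = ".")
  res$p_adj <- NA_real_
  for (f in unique(res$family)) {
    i <- which(res$family == f & res$k >= 2 & is.finite(res$p))
    if (length(i)) res$p_adj[i] <- bh_adjust(res$p[i])
  }
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}
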