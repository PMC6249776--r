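## Per-cohort association testing. Glycan variables and continuous
## covariates are mapped to the standard normal by rank-based inverse
## normal transformation, then modelled with logistic regression (disease
## status ~ glycan + age + sex) or a general linear model (glycan ~
## clinical feature + age + sex). Models are fitted by the module's own
## IRLS / least-squares routines so the numerics are fully specified.

#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to approximate standard-normal scores:
#' `qnorm((r - 0.5) / n)` with average ranks for ties (the convention of
#' the GenABEL `rntransform` routine). Effects estimated on transformed
#' variables are read in SD units. A Blom offset `(r - 3/8) / (n + 1/4)`
#' is available behind a flag.
#'
#' @param x numeric vector, finite
#' @param offset `"half"` (default) or `"blom"`
#' @return numeric vector of normal scores
#' @export
#' @examples
#' rank_int(c(5, 1, 9))  # 0, -0.967, 0.967
rank_int <- function(x, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  assert_that(length(x) >= 1 && all(is.finite(x)),
              "rank_int needs finite values")
  r <- rank(x, ties.method = "average")
  n <- length(x)
  if (offset == "half") qnorm((r - 0.5) / n)
  else qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit with Newton/IRLS steps, convergence when the
#' largest coefficient change falls below `tol` (default 1e-8) within
#' `max_iter` iterations. Standard errors come from the observed
#' information at the optimum; p-values are two-sided Wald normal.
#' Complete separation (a coefficient diverging beyond 15 on the logit
#' scale, or non-convergence) is flagged and the p-values set to `NA`
#' rather than reporting a spurious result.
#'
#' @param y binary 0/1 response
#' @param X design matrix including the intercept column
#' @param tol convergence tolerance on the coefficient change
#' @param max_iter maximum IRLS iterations
#' @return list with `beta`, `se`, `p` (named per column), `converged`,
#'   `separation`, `n`, `iterations`
#' @export
fit_logistic <- function(y, X, tol = 1e-8, max_iter = 25L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  assert_that(nrow(X) == length(y), "X rows must match y")
  assert_that(nrow(X) > ncol(X), "need more observations than parameters")
  assert_that(qr(X)$rank == ncol(X), "design matrix is rank deficient")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    w <- pmax(w, 1e-10)
    XtW <- t(X * w)
    step <- tryCatch(solve(XtW %*% X, t(X) %*% (y - p)),
                     error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p_hat <- 1 / (1 + exp(-eta))
  w <- pmax(p_hat * (1 - p_hat), 1e-10)
  info <- t(X * w) %*% X
  se <- sqrt(diag(tryCatch(solve(info), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))))
  separation <- !converged || any(abs(beta) > 15)
  pv <- if (separation) rep(NA_real_, ncol(X)) else
    2 * pnorm(-abs(beta / se))
  list(beta = setNames(drop(beta), colnames(X)),
       se = setNames(se, colnames(X)),
       p = setNames(pv, colnames(X)),
       converged = converged, separation = separation,
       n = length(y), iterations = it)
}

#' Ordinary least squares with t-based Wald inference
#'
#' Closed-form normal-equations fit via QR; standard errors from
#' `sigma^2 (X'X)^{-1}` with `df = n - ncol(X)`; two-sided t p-values.
#'
#' @param y numeric response
#' @param X design matrix including the intercept column
#' @return list with `beta`, `se`, `p`, `sigma2`, `df`, `n`
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  assert_that(nrow(X) == length(y), "X rows must match y")
  assert_that(nrow(X) > ncol(X) + 1, "need n > parameters + 1")
  qx <- qr(X)
  assert_that(qx$rank == ncol(X), "design matrix is rank deficient")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(sigma2 * diag(XtX_inv), 0))
  tval <- beta / se
  pv <- 2 * pt(-abs(tval), df)
  pv[se == 0] <- ifelse(abs(beta[se == 0]) < 1e-12, 1, 0)
  list(beta = setNames(drop(beta), colnames(X)),
       se = setNames(se, colnames(X)),
       p = setNames(pv, colnames(X)),
       sigma2 = sigma2, df = df, n = length(y))
}

assoc_row <- function(variable, var_type, panel, cohort, model, feature,
                      level, fit, term) {
  data.frame(variable = variable, var_type = var_type, panel = panel,
             cohort = cohort, model = model, feature = feature,
             level = level, beta = unname(fit$beta[term]),
             se = unname(fit$se[term]), p = unname(fit$p[term]),
             n = fit$n,
             flag = if (isTRUE(fit$separation)) "separation" else "",
             stringsAsFactors = FALSE)
}

glycan_frame <- function(glycans) {
  g <- as.data.frame(glycans)
  assert_that(ncol(g) >= 1, "no glycan variables supplied")
  g
}

base_covariates <- function(phen) {
  assert_that(all(c("age", "sex") %in% names(phen)),
              "phenotypes need age and sex")
  assert_that(all(stats::complete.cases(phen[, c("age", "sex")])),
              "age and sex must be complete")
  cbind(age = rank_int(phen$age), sex = as.numeric(phen$sex == "M"))
}

#' Case-control association of glycan variables within one cohort
#'
#' For each glycan column: the glycan (and age) are inverse-normal
#' transformed within the cohort, then
#' `status ~ glycan + age + sex` is fitted by [fit_logistic()]. The
#' emitted effect is the glycan coefficient: a log odds ratio per SD of
#' glycan abundance.
#'
#' @param glycans data frame or matrix of glycan variables (peaks and/or
#'   derived traits), rows aligned with `phen`
#' @param phen phenotype data frame with columns `status` (0/1), `age`,
#'   `sex` (`"M"`/`"F"`)
#' @param cohort cohort identifier copied to the result rows
#' @param var_type label for the result rows (`"derived"` or `"peak"`)
#' @param panel panel tag copied to the result rows
#' @return data frame of association rows (one per glycan)
#' @export
associate_case_control <- function(glycans, phen, cohort = 1,
                                   var_type = "derived",
                                   panel = NA_character_) {
  g <- glycan_frame(glycans)
  assert_that(nrow(g) == nrow(phen), "glycans and phenotypes must align")
  y <- phen$status
  assert_that(length(unique(y)) == 2,
              "cohort must contain both cases and controls")
  cov <- base_covariates(phen)
  out <- lapply(names(g), function(v) {
    X <- cbind(intercept = 1, glycan = rank_int(g[[v]]), cov)
    fit <- fit_logistic(y, X)
    assoc_row(v, var_type, panel, cohort, "logistic", "status", NA, fit,
              "glycan")
  })
  do.call(rbind, out)
}

#' Association of glycans with a clinical feature within one cohort
#'
#' Fits `glycan ~ feature + age + sex` by [fit_linear()], with the glycan
#' (dependent variable) and any continuous feature inverse-normal
#' transformed within cohort. Categorical features are coded against a
#' referent: healthy controls for case-only severity features (GOLD
#' stage, ABCD group, exacerbation category), or an explicit referent
#' level (e.g. never-smokers). One row is emitted per non-referent level;
#' levels with fewer than 3 subjects are skipped with a flag.
#'
#' @inheritParams associate_case_control
#' @param feature column of `phen` to test
#' @param kind `"categorical"` or `"continuous"`
#' @param referent referent level for categorical features; `"control"`
#'   means the healthy controls (subjects with `status == 0`)
#' @return data frame of association rows (glycan x level)
#' @export
associate_feature <- function(glycans, phen, feature,
                              kind = c("categorical", "continuous"),
                              cohort = 1, referent = "control",
                              var_type = "derived",
                              panel = NA_character_) {
  kind <- match.arg(kind)
  g <- glycan_frame(glycans)
  assert_that(feature %in% names(phen), "feature '%s' not found", feature)
  assert_that(nrow(g) == nrow(phen), "glycans and phenotypes must align")

  if (kind == "continuous") {
    keep <- is.finite(phen[[feature]])
    phen2 <- phen[keep, , drop = FALSE]
    cov <- base_covariates(phen2)
    fx <- rank_int(phen2[[feature]])
    out <- lapply(names(g), function(v) {
      X <- cbind(intercept = 1, feature = fx, cov)
      fit <- fit_linear(rank_int(g[[v]][keep]), X)
      assoc_row(v, var_type, panel, cohort, "linear", feature, NA, fit,
                "feature")
    })
    return(do.call(rbind, out))
  }

  fval <- as.character(phen[[feature]])
  if (identical(referent, "control")) {
    keep <- phen$status == 0 | !is.na(fval)
    base <- phen$status == 0
  } else {
    keep <- !is.na(fval)
    base <- fval == referent
  }
  phen2 <- phen[keep, , drop = FALSE]
  fval <- fval[keep]; base <- base[keep]
  levels_present <- sort(unique(fval[!base & !is.na(fval)]))
  sizes <- table(factor(fval[!base], levels = levels_present))
  usable <- names(sizes)[sizes >= 3]
  skipped <- setdiff(levels_present, usable)
  sel <- base | fval %in% usable
  phen2 <- phen2[sel, , drop = FALSE]
  fval <- fval[sel]; base <- base[sel]
  assert_that(sum(base) >= 3, "referent group has fewer than 3 subjects")
  assert_that(length(usable) >= 1, "no usable levels for feature '%s'",
              feature)
  dummies <- sapply(usable, function(l) as.numeric(!base & fval == l))
  colnames(dummies) <- usable
  cov <- base_covariates(phen2)
  out <- lapply(names(g), function(v) {
    X <- cbind(intercept = 1, dummies, cov)
    fit <- fit_linear(rank_int(g[[v]][keep][sel]), X)
    rows <- do.call(rbind, lapply(usable, function(l)
      assoc_row(v, var_type, panel, cohort, "linear", feature, l, fit, l)))
    rows
  })
  res <- do.call(rbind, out)
  attr(res, "skipped_levels") <- skipped
  res
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed the observed table's
#' (the standard two-sided convention).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins
#' @return two-sided p-value
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(49, 86, 46, 51), 2))  # ~0.105
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2, 2)), "need a 2x2 table")
  assert_that(all(table >= 0) && all(table == round(table)),
              "cells must be non-negative integers")
  assert_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "all margins must be positive")
  fisher.test(table)$p.value
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration p-value when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples, each non-empty
#' @return list with `U` (Mann-Whitney statistic for `x`) and `p`
#'   (two-sided), plus `method`
#' @export
wilcoxon_rank_sum <- function(x, y) {
  assert_that(length(x) >= 1 && length(y) >= 1, "both groups non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal-approximation")
}

#' Cohort descriptive table with group comparison tests
#'
#' Summarises each configured variable per group (median and IQR with a
#' Wilcoxon rank-sum test for continuous variables; N (%) with a Fisher
#' exact test for categorical ones). Case-only variables (GOLD stage,
#' ABCD group, exacerbations) are tabulated without a test. 2xk tables
#' with k <= 3 and moderate n use the exact network algorithm; larger
#' tables fall back to a seeded Monte-Carlo p-value.
#'
#' @param phen phenotype data frame for one cohort
#' @param continuous,categorical,case_only character vectors of variable
#'   names
#' @param seed seed for Monte-Carlo Fisher p-values
#' @return data frame with columns `variable`, `level`,
#'   `control_summary`, `case_summary`, `test`, `p`
#' @export
describe_cohorts <- function(phen,
    continuous = c("age", "hscrp", "fibrinogen", "fvc", "fev1",
                   "fev1_fvc"),
    categorical = c("sex", "smoking"),
    case_only = c("gold", "abcd", "exacerbations"),
    seed = 1L) {
  ctrl <- phen[phen$status == 0, , drop = FALSE]
  case <- phen[phen$status == 1, , drop = FALSE]
  fmt_med <- function(v) sprintf("%.2f (%.2f-%.2f)", median(v),
                                 quantile(v, 0.25), quantile(v, 0.75))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  for (v in continuous) {
    if (!v %in% names(phen)) next
    x0 <- ctrl[[v]]; x1 <- case[[v]]
    constant <- length(unique(c(x0, x1))) == 1
    p <- if (constant) 1 else wilcoxon_rank_sum(x0, x1)$p
    add(variable = v, level = NA_character_,
        control_summary = fmt_med(x0), case_summary = fmt_med(x1),
        test = if (constant) "constant" else "wilcoxon", p = p)
  }
  for (v in categorical) {
    if (!v %in% names(phen)) next
    lv <- sort(unique(as.character(phen[[v]])))
    tab <- rbind(table(factor(ctrl[[v]], levels = lv)),
                 table(factor(case[[v]], levels = lv)))
    lv <- lv[colSums(tab) > 0]
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    p <- if (ncol(tab) == 2) {
      fisher_exact_2x2(t(tab))
    } else if (ncol(tab) <= 3 && sum(tab) <= 1000) {
      fisher.test(tab)$p.value
    } else {
      withr::with_seed(seed,
        fisher.test(tab, simulate.p.value = TRUE, B = 10000)$p.value)
    }
    for (i in seq_along(lv)) {
      add(variable = v, level = lv[i],
          control_summary = sprintf("%d (%.0f%%)", tab[1, i],
                                    100 * tab[1, i] / nrow(ctrl)),
          case_summary = sprintf("%d (%.0f%%)", tab[2, i],
                                 100 * tab[2, i] / nrow(case)),
          test = "fisher", p = if (i == 1) p else NA_real_)
    }
  }
  for (v in case_only) {
    if (!v %in% names(phen)) next
    lv <- sort(unique(stats::na.omit(as.character(case[[v]]))))
    for (l in lv) {
      n <- sum(case[[v]] == l, na.rm = TRUE)
      add(variable = v, level = l, control_summary = "",
          case_summary = sprintf("%d (%.0f%%)", n, 100 * n / nrow(case)),
          test = "none", p = NA_real_)
    }
  }
  do.call(rbind, rows)
}
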