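# Rank-INT, the in-package logistic/linear fitters, Fisher and Wilcoxon
# tests, and the cohort association surfaces.

test_that("rank-INT matches the normal-quantile oracle, with average ranks for ties", {
  expect_equal(rank_int(c(5, 1, 9)), qnorm(c(3, 1, 5) / 6),
               tolerance = 1e-3)
  expect_equal(rank_int(7), 0)
  expect_equal(rank_int(c(1, 1, 2)),
               qnorm(c(1.5, 1.5, 3) / 3 - 0.5 / 3), tolerance = 1e-3)
  expect_equal(rank_int(c(1, 1, 2)),
               c(qnorm(1 / 3), qnorm(1 / 3), qnorm(5 / 6)),
               tolerance = 1e-9)
})

test_that("rank-INT has mean zero and is invariant to monotone transforms", {
  withr::with_seed(2, x <- rnorm(101))
  y <- rank_int(x)
  expect_lt(abs(mean(y)), 1e-9)
  expect_equal(rank_int(exp(3 * x + 1)), y, tolerance = 1e-12)
  expect_equal(rank_int(x, offset = "blom"),
               qnorm((rank(x) - 3 / 8) / (length(x) + 0.25)))
  expect_error(rank_int(c(1, NA)), "finite")
})

test_that("IRLS logistic matches closed forms and a brute-force MLE oracle", {
  f <- fit_logistic(c(0, 0, 1, 1), matrix(1, 4, 1))
  expect_equal(unname(f$beta), 0, tolerance = 1e-6)
  expect_equal(unname(f$se), 1, tolerance = 1e-6)

  # 8-point dataset against a derivative-free likelihood optimiser
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  X <- cbind(1, c(-1.2, -0.8, -0.5, 0.1, 0.4, 0.9, 1.3, 1.8),
             c(0, 1, 0, 1, 1, 0, 0, 1))
  f2 <- fit_logistic(y, X)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log(1 + exp(eta)))
  }
  oracle <- optim(c(0, 0, 0), nll, method = "BFGS",
                  control = list(reltol = 1e-14))$par
  expect_equal(unname(f2$beta), oracle, tolerance = 1e-6)
  # and against R's glm as a second, independent implementation
  g <- glm(y ~ X - 1, family = binomial())
  expect_equal(unname(f2$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f2$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("logistic null coefficient stays within 3 SE and separation is flagged", {
  withr::with_seed(11, {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, 0.5)
  })
  f <- fit_logistic(y, cbind(1, x))
  expect_lt(abs(f$beta[2]), 3 * f$se[2])
  # perfectly separated data must flag, not report a tiny p
  xs <- c(-2, -1.5, -1, 1, 1.5, 2)
  ys <- c(0, 0, 0, 1, 1, 1)
  fs <- fit_logistic(ys, cbind(1, xs))
  expect_true(fs$separation)
  expect_true(all(is.na(fs$p)))
})

test_that("logistic and linear fits are equivariant to affine covariate rescaling", {
  withr::with_seed(13, {
    x <- rnorm(300); z <- rnorm(300)
    y <- rbinom(300, 1, plogis(0.3 * x))
    yl <- 0.5 * x + rnorm(300)
  })
  f1 <- fit_logistic(y, cbind(1, x, z))
  f2 <- fit_logistic(y, cbind(1, 10 * x + 3, z))
  expect_equal(unname(f1$beta[2]), unname(10 * f2$beta[2]),
               tolerance = 1e-6)
  expect_equal(unname(f1$p[2]), unname(f2$p[2]), tolerance = 1e-9)
  l1 <- fit_linear(yl, cbind(1, x, z))
  l2 <- fit_linear(yl, cbind(1, 10 * x + 3, z))
  expect_equal(unname(l1$beta[2]), unname(10 * l2$beta[2]),
               tolerance = 1e-10)
  expect_equal(unname(l1$p[2]), unname(l2$p[2]), tolerance = 1e-9)
})

test_that("OLS matches lm and handles exact fits and orthogonal covariates", {
  x <- c(1, 2, 3, 4, 5, 6)
  f <- fit_linear(2 * x, cbind(1, x))
  expect_equal(unname(f$beta), c(0, 2), tolerance = 1e-12)
  expect_equal(f$sigma2, 0, tolerance = 1e-20)

  withr::with_seed(17, {
    X <- cbind(1, rnorm(40), rnorm(40))
    y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(40)
  })
  f2 <- fit_linear(y, X)
  l <- lm(y ~ X - 1)
  expect_equal(unname(f2$beta), unname(coef(l)), tolerance = 1e-10)
  expect_equal(unname(f2$se), unname(summary(l)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(f2$p), unname(summary(l)$coefficients[, 4]),
               tolerance = 1e-10)
  # adding an exactly orthogonal covariate leaves the slope unchanged
  x1 <- c(-1, 1, -1, 1); x2 <- c(-1, -1, 1, 1); yy <- c(1, 3, 2, 5)
  # need n > p + 1: replicate the orthogonal design
  x1 <- rep(x1, 3); x2 <- rep(x2, 3); yy <- rep(yy, 3) + 0.01 * (1:12)
  b_without <- fit_linear(yy, cbind(1, x1))$beta[2]
  b_with <- fit_linear(yy, cbind(1, x1, x2))$beta[2]
  expect_equal(unname(b_without), unname(b_with), tolerance = 1e-10)
})

test_that("Fisher's exact test matches enumeration and is symmetric", {
  tab <- matrix(c(49, 86, 46, 51), 2)  # discovery-cohort sex table
  expect_lt(abs(fisher_exact_2x2(tab) - 0.105), 1e-3)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(t(tab)), fisher_exact_2x2(tab))
  expect_equal(fisher_exact_2x2(tab[2:1, ]), fisher_exact_2x2(tab))
  expect_equal(fisher_exact_2x2(tab[, 2:1]), fisher_exact_2x2(tab))
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Wilcoxon rank-sum: exact small-sample branch and calibration", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p, 1 / 3, tolerance = 1e-12)
  expect_equal(w$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 1, 2, 3), c(1, 2, 3, 1))
  expect_gte(same$p, 0.99)
  # null rejection rate within +/- 0.02 of 0.05
  withr::with_seed(19, {
    rej <- mean(replicate(1000, {
      wilcoxon_rank_sum(rnorm(15), rnorm(15))$p < 0.05
    }))
  })
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("case-control association reports log-OR per SD with information scaling", {
  cfg <- small_config(n1 = c(60, 20), n0 = c(60, 20),
                      effect_map = c(G1 = -0.8), seed = 31)
  sim <- simulate_cohorts(cfg)
  i <- sim$peaks$cohort == 1
  pk <- peak_names("igg")
  tr <- compute_derived_traits(
    as.matrix(sim$peaks[i, pk]), load_trait_definitions("igg"))
  ph <- sim$phenotypes[i, ]
  res <- associate_case_control(as.data.frame(tr), ph, cohort = 1,
                                panel = "igg")
  expect_equal(nrow(res), 9)
  g1 <- res[res$variable == "G1", ]
  expect_lt(g1$beta, 0)
  # duplicating every subject scales the SE by ~1/sqrt(2)
  res2 <- associate_case_control(as.data.frame(tr[rep(1:nrow(tr), 2), ]),
                                 ph[rep(1:nrow(ph), 2), ], cohort = 1,
                                 panel = "igg")
  expect_equal(res2[res2$variable == "G1", "se"] * sqrt(2), g1$se,
               tolerance = 0.02)
  expect_error(associate_case_control(as.data.frame(tr),
                                      transform(ph, status = 1)),
               "cases and controls")
})

test_that("type-I error of the case-control path is calibrated at the 5% level", {
  ps <- c()
  for (s in 1:15) {
    cfg <- small_config(n1 = c(100), n0 = c(100), seed = 600 + s,
                        batch_shift_sd = 0, batch_scale_sd = 0,
                        n_batches_per_cohort = 1)
    sim <- simulate_cohorts(cfg)
    pk <- peak_names("igg")
    g <- cbind(
      as.data.frame(compute_derived_traits(as.matrix(sim$peaks[, pk]),
                                           load_trait_definitions("igg"))),
      sim$peaks[, pk])
    res <- associate_case_control(g, sim$phenotypes, panel = "igg")
    ps <- c(ps, res$p)
  }
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("feature associations recover injected structure", {
  # smoking effect present in current smokers, attenuated in ex-smokers
  cfg <- small_config(n1 = c(150), n0 = c(150), seed = 77,
                      smoking_effect_map = c(CoreF = -0.8),
                      ex_smoker_attenuation = 0.4)
  sim <- simulate_cohorts(cfg)
  pk <- peak_names("igg")
  tr <- compute_derived_traits(as.matrix(sim$peaks[, pk]),
                               load_trait_definitions("igg"))
  res <- associate_feature(as.data.frame(tr), sim$phenotypes, "smoking",
                           kind = "categorical", referent = "never",
                           panel = "igg")
  cur <- res[res$variable == "CoreF" & res$level == "current", ]
  ex <- res[res$variable == "CoreF" & res$level == "ex", ]
  expect_lt(cur$beta, 0)
  expect_lt(abs(ex$beta), abs(cur$beta))

  # a binary feature with equal group means gives beta ~ 0
  withr::with_seed(5, {
    ph0 <- data.frame(status = rep(0:1, each = 50),
                      age = rnorm(100, 60, 8),
                      sex = sample(c("M", "F"), 100, replace = TRUE),
                      grp = rep(c("a", "b"), 50))
    g0 <- data.frame(v = rnorm(100))
  })
  r0 <- associate_feature(g0, ph0, "grp", kind = "categorical",
                          referent = "a")
  expect_lt(abs(r0$beta), 3 * r0$se)
})

test_that("GOLD-graded effects yield monotone stage contrasts on average", {
  betas <- matrix(NA_real_, 10, 3, dimnames = list(NULL, c("2", "3", "4")))
  for (s in 1:10) {
    cfg <- small_config(panel = "plasma", n1 = c(200), n0 = c(150),
                        seed = 900 + s, effect_map = c(G4 = 0.6),
                        gold_dose = c(`1` = 0.25, `2` = 0.5, `3` = 1,
                                      `4` = 1.5))
    sim <- simulate_cohorts(cfg)
    tr <- compute_derived_traits(
      as.matrix(sim$peaks[, peak_names("plasma")]),
      load_trait_definitions("plasma"))
    res <- associate_feature(as.data.frame(tr[, "G4", drop = FALSE]),
                             sim$phenotypes, "gold",
                             kind = "categorical", referent = "control",
                             panel = "plasma")
    for (l in colnames(betas)) {
      b <- res$beta[res$level == l]
      if (length(b)) betas[s, l] <- b
    }
  }
  m <- colMeans(betas, na.rm = TRUE)
  expect_true(m["2"] < m["3"] && m["3"] < m["4"])
})

test_that("cohort descriptives reproduce the printed sex comparison", {
  cfg <- sim_config(seed = 1)  # default two-cohort design
  sim <- simulate_cohorts(cfg)
  ph1 <- sim$phenotypes[sim$phenotypes$cohort == 1, ]
  # exact male counts from the configured fractions: 86/137 vs 49/95
  expect_equal(sum(ph1$sex == "M" & ph1$status == 1), 86)
  expect_equal(sum(ph1$sex == "M" & ph1$status == 0), 49)
  d <- describe_cohorts(ph1)
  psex <- d$p[d$variable == "sex" & !is.na(d$p)]
  expect_lt(abs(psex - 0.105), 1e-3)
  expect_equal(psex, fisher_exact_2x2(matrix(c(49, 86, 46, 51), 2)))
  # constant variable branch
  ph1$fibrinogen <- 3.5
  d2 <- describe_cohorts(ph1)
  expect_equal(d2$p[d2$variable == "fibrinogen"], 1)
  expect_equal(d2$test[d2$variable == "fibrinogen"], "constant")
  # one row per configured variable/level
  expect_true(all(c("age", "sex", "smoking", "gold") %in% d$variable))
})
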