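# The two-cohort simulator: determinism, compositional closure, null
# behaviour, batch-effect truth and dose monotonicity.

test_that("simulation is fully determined by the seed", {
  cfg <- small_config(seed = 5)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohorts(small_config(seed = 6))
  expect_false(identical(a$peaks, c2$peaks))
})

test_that("peak vectors are strictly positive and close to 100", {
  sim <- simulate_cohorts(small_config(panel = "plasma", seed = 12,
                                       effect_map = c(G1 = -0.5)))
  pk <- as.matrix(sim$peaks[, peak_names("plasma")])
  expect_true(all(pk > 0))
  expect_equal(rowSums(pk), rep(100, nrow(pk)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(nrow(pk), sum(20 + 20, 20 + 20))
  # phenotype schema
  expect_true(all(c("subject_id", "cohort", "status", "age", "sex",
                    "smoking", "pack_years", "gold", "abcd",
                    "exacerbations", "fev1", "fvc", "fev1_fvc", "hscrp",
                    "fibrinogen") %in% names(sim$phenotypes)))
  expect_true(all(is.na(sim$phenotypes$gold[sim$phenotypes$status == 0])))
})

test_that("config validation rejects impossible designs and unknown keys", {
  expect_error(small_config(effect_map = c(NotATrait = 1)),
               "effect map keys")
  expect_error(small_config(n1 = c(1, 20), n0 = c(20, 20)), "at least 2")
  expect_error(small_config(n1 = c(4, 4), n0 = c(4, 4),
                            n_batches_per_cohort = 5), "batch sizes")
  expect_error(sim_config(panel = "serum"), "arg")
})

test_that("null simulation shows no systematic trait differences", {
  cfg <- small_config(panel = "igg", n1 = c(100), n0 = c(100),
                      seed = 21, batch_shift_sd = 0,
                      batch_scale_sd = 0, n_batches_per_cohort = 1)
  sim <- simulate_cohorts(cfg)
  tr <- compute_derived_traits(as.matrix(sim$peaks[, peak_names("igg")]),
                               load_trait_definitions("igg"))
  case <- sim$phenotypes$status == 1
  for (v in colnames(tr)) {
    d <- mean(tr[case, v]) - mean(tr[!case, v])
    se <- sqrt(var(tr[case, v]) / sum(case) +
               var(tr[!case, v]) / sum(!case))
    expect_lt(abs(d), 3 * se)
  }
})

test_that("batch effects match their recorded truth and vanish at zero SD", {
  withr::with_seed(3, x <- matrix(rnorm(400 * 10, 2, 0.3), 400,
                                  dimnames = list(NULL, paste0("P", 1:10))))
  batches <- rep(c("a", "b"), each = 200)
  same <- apply_batch_effects(x, batches, 0, 0, seed = 4)
  expect_equal(unname(same), unname(x), tolerance = 1e-15,
               ignore_attr = TRUE)
  # one batch: a constant per-peak shift
  one <- apply_batch_effects(x, rep("a", 400), shift_sd = 1,
                             scale_sd = 0, seed = 5)
  truth1 <- attr(one, "truth")
  expect_equal(unname(one - x),
               matrix(truth1$shift["a", ], 400, 10, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # two batches: observed batch mean gap reproduces the drawn shifts
  two <- apply_batch_effects(x, batches, shift_sd = 1, scale_sd = 0,
                             seed = 6)
  truth2 <- attr(two, "truth")
  gap_obs <- colMeans(two[batches == "b", ]) -
    colMeans(two[batches == "a", ])
  gap_true <- truth2$shift["b", ] - truth2$shift["a", ]
  se <- 0.3 * sqrt(2 / 200)
  expect_true(all(abs(gap_obs - gap_true) < 3 * se))
  expect_error(apply_batch_effects(x, c("a", rep("b", 399)), 1, 0, 1),
               "at least 2")
})

test_that("a single-cohort estimate recovers an injected trait effect", {
  cfg <- small_config(panel = "igg", n1 = c(500), n0 = c(500),
                      seed = 55, effect_map = c(G1 = -0.5))
  res <- simulate_and_run(cfg, include_peaks = FALSE)
  g1 <- res$assoc[res$assoc$variable == "G1", ]
  expect_equal(g1$beta, -0.5, tolerance = 0.15)
})

test_that("larger injected effects never shrink the recovered effect (dose monotonicity)", {
  doses <- c(0, 0.25, 0.5)
  mean_abs <- sapply(doses, function(d) {
    est <- sapply(1:6, function(s) {
      em <- if (d == 0) c() else c(G1 = -d)
      cfg <- small_config(panel = "igg", n1 = c(250), n0 = c(250),
                          seed = 7000 + s, effect_map = em,
                          batch_shift_sd = 0, batch_scale_sd = 0,
                          n_batches_per_cohort = 1)
      sim <- simulate_cohorts(cfg)
      tr <- compute_derived_traits(
        as.matrix(sim$peaks[, peak_names("igg")]),
        load_trait_definitions("igg"))
      res <- associate_case_control(
        as.data.frame(tr[, "G1", drop = FALSE]), sim$phenotypes,
        panel = "igg")
      res$beta
    })
    mean(abs(est))
  })
  expect_true(mean_abs[1] <= mean_abs[2] && mean_abs[2] <= mean_abs[3])
})

test_that("simulated datasets round-trip through the CSV writer", {
  sim <- simulate_cohorts(small_config(seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[1], stringsAsFactors = FALSE)
  expect_equal(back$subject_id, sim$peaks$subject_id)
  expect_equal(back$IGP1, sim$peaks$IGP1, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[3])
  expect_equal(truth$panel, "igg")
})
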