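test_that("cohort demographics match the published distributions", {
  cov <- generate_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(cov), 82)
  expect_lt(abs(mean(cov$AGE) - 65.7), 4)
  expect_true(all(cov$AGE >= 22 & cov$AGE <= 93))
  expect_true(all(cov$WT >= 44.2 & cov$WT <= 195))
  expect_true(all(cov$HT >= 149.9 & cov$HT <= 187.9))
  expect_true(all(cov$SCR >= 0.4 & cov$SCR <= 3.8))
  expect_true(all(cov$FPG >= 76 & cov$FPG <= 251))
  expect_true(all(c("BMI", "IBW", "ABW", "LBW", "EGFR", "CRCL", "OBESE",
                    "METCAT", "AKI") %in% names(cov)))
})

test_that("binary covariate rates converge to the published fractions", {
  cov <- generate_cohort(cohort_config(n = 10000), seed = 2)
  expect_lt(abs(mean(cov$DM) - 0.317), 0.02)
  expect_lt(abs(mean(cov$AKI) - 0.219), 0.02)
  expect_lt(abs(mean(cov$SEX == "female") - 0.622), 0.02)
  expect_lt(abs(mean(cov$RACE == "black") - 0.073), 0.01)
  # the diabetes-linked shifts induce the reported gradient
  expect_gt(mean(cov$WT[cov$DM]), mean(cov$WT[!cov$DM]))
  expect_gt(mean(cov$FPG[cov$DM]), mean(cov$FPG[!cov$DM]))
  expect_lt(mean(cov$EGFR[cov$DM]), mean(cov$EGFR[!cov$DM]))
})

test_that("the same seed reproduces the cohort and the whole dataset", {
  expect_identical(generate_cohort(cohort_config(), seed = 3),
                   generate_cohort(cohort_config(), seed = 3))
  d1 <- synthetic_dataset(cohort_config(), final_model(), seed = 4)
  d2 <- synthetic_dataset(cohort_config(), final_model(), seed = 4)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("stored truth re-simulates the identical dataset", {
  cfg <- cohort_config(n = 25)
  cohort <- generate_cohort(cfg, seed = 11)
  design <- generate_design(cohort, cfg, seed = 12)
  d1 <- simulate_concentrations(design, cohort, final_model(), seed = 13)
  tr <- attr(d1, "truth")
  d2 <- simulate_concentrations(design, cohort, tr$model, seed = tr$seed)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(attr(d2, "truth")$eta, tr$eta)
})

test_that("the TDM design emulates the cohort's sampling intensity", {
  cfg <- cohort_config()
  cohort <- generate_cohort(cfg, seed = 5)
  design <- generate_design(cohort, cfg, seed = 6)
  n_obs <- sum(vapply(design, function(d) length(d$sample_times), 0L))
  expect_gte(n_obs, 82); expect_lte(n_obs, 164)

  big <- generate_design(generate_cohort(cohort_config(n = 10000), seed = 7),
                         cohort_config(n = 10000), seed = 8)
  counts <- vapply(big, function(d) length(d$sample_times), 0L)
  expect_lt(abs(mean(counts) - 1.15), 0.02)
  doses <- vapply(big, function(d) d$doses$amount[1], 0)
  expect_equal(stats::median(doses), 300)
  expect_true(all(range(doses) == c(100, 1200)))
  # every sample strictly after that subject's first dose
  expect_true(all(vapply(big, function(d)
    all(d$sample_times > d$doses$time[1]), TRUE)))
})

test_that("noise-free simulation equals the typical-subject closed form", {
  quiet <- pop_model(init = c(V = 44.61, Cl = 5.73),
                     fixed = c(ka = 0.778, tlag = 0),
                     omega = c(), omega_fixed = c(V = 1e-9, Cl = 1e-9),
                     error = error_model("constant", a = 1e-12))
  cohort <- data.frame(ID = c("a", "b"), SCR = c(1.3, 1.3))
  design <- list(
    list(id = "a", doses = data.frame(time = 0, amount = 300),
         sample_times = c(3, 11)),
    list(id = "b", doses = data.frame(time = c(0, 8), amount = c(300, 300)),
         sample_times = 11))
  d <- simulate_concentrations(design, cohort, quiet, seed = 1)
  p <- structural_params(V = 44.61, Cl = 5.73, ka = 0.778)
  expect_equal(d$subjects[["a"]]$observations$conc,
               conc_first_order(c(3, 11), data.frame(time = 0, amount = 300),
                                p),
               tolerance = 1e-6)
  expect_equal(d$subjects[["b"]]$observations$conc,
               conc_first_order(11, data.frame(time = c(0, 8),
                                               amount = c(300, 300)), p),
               tolerance = 1e-6)
})

test_that("steady-state population mean agrees with an independent
           Monte-Carlo expectation", {
  n <- 4000
  cohort <- data.frame(ID = sprintf("m%04d", 1:n), SCR = rep(1.3, n))
  dose_times <- seq(0, 96, by = 8)
  design <- lapply(1:n, function(i) {
    list(id = cohort$ID[i],
         doses = data.frame(time = dose_times,
                            amount = rep(300, length(dose_times))),
         sample_times = 99)
  })
  truth <- final_model()
  d <- simulate_concentrations(design, cohort, truth, seed = 51)
  sim_mean <- mean(vapply(d$subjects, function(s) s$observations$conc, 0))
  # independent expectation: fresh eta draws through the closed form
  set.seed(99)
  etaV <- rnorm(n, 0, 0.77); etaCl <- rnorm(n, 0, 0.28)
  ref <- mean(vapply(seq_len(n), function(i) {
    p <- structural_params(V = 44.61 * exp(etaV[i]),
                           Cl = 5.73 * exp(etaCl[i]), ka = 0.778)
    conc_steady_state(3, 300, 8, p)
  }, 0))
  expect_lt(abs(sim_mean - ref) / ref, 0.10)
})

test_that("most simulated TDM concentrations fall in the assay reference
           range 2-20 ug/mL", {
  d <- synthetic_dataset(cohort_config(n = 600), final_model(), seed = 23)
  y <- as.data.frame(d)
  y <- y$DV[y$EVID == 0]
  expect_gt(mean(y >= 2 & y <= 20), 0.60)
})

test_that("impossible truncation bounds are rejected", {
  expect_error(cohort_config(age = c(65, 16, 93, 22)), "truncation")
})
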