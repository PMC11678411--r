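base_search_model <- function() {
  pop_model(init = c(V = 45.4, Cl = 6.31), fixed = c(ka = 0.778, tlag = 0),
            omega = c(V = 0.5, Cl = 0.3),
            error = error_model("constant", a = 1))
}

test_that("a strongly simulated creatinine effect passes all three gates
           and a pure-noise covariate fails them", {
  d <- synthetic_dataset(cohort_config(), final_model(), seed = 5)
  # graft an independent noise covariate onto every subject
  set.seed(404)
  for (i in seq_along(d$subjects)) {
    d$subjects[[i]]$covariates$NOISE <- exp(rnorm(1))
  }
  ctl <- saem_control(150, 75)
  bf <- fit_saem(d, base_search_model(), ctl, seed = 11)

  tr <- test_covariate(d, bf, "SCR", "Cl", ctl, n_samples = 400)
  expect_true(tr$accepted)
  expect_gte(tr$dofv, 3.84)
  expect_lte(tr$wald_p, 0.01)
  expect_lte(tr$corr_p, 0.01)
  expect_lt(tr$beta, 0)  # clearance falls as creatinine rises

  tn <- test_covariate(d, bf, "NOISE", "Cl", ctl, n_samples = 400)
  expect_false(tn$accepted)
})

test_that("acceptance is the conjunction of the three gates", {
  # decision recomputable from the reported statistics
  d <- synthetic_dataset(cohort_config(n = 40), final_model(), seed = 9)
  ctl <- saem_control(100, 50)
  bf <- fit_saem(d, base_search_model(), ctl, seed = 2)
  tst <- test_covariate(d, bf, "SCR", "Cl", ctl, n_samples = 300)
  expect_identical(tst$accepted,
                   isTRUE(tst$dofv >= 3.84) && isTRUE(tst$wald_p <= 0.01) &&
                     isTRUE(tst$corr_p <= 0.01))
})

test_that("correlation screen flags an omitted generating covariate and
           degrades gracefully on constant columns", {
  d <- synthetic_dataset(cohort_config(), final_model(), seed = 6)
  for (i in seq_along(d$subjects)) d$subjects[[i]]$covariates$CONST <- 1
  fit <- fit_saem(d, base_search_model(), saem_control(150, 75), seed = 3)
  sc <- correlation_screen(fit, d, covariates = c("SCR", "CONST"))
  expect_true(sc$flagged[sc$covariate == "SCR" & sc$random_effect == "Cl"])
  const_rows <- sc[sc$covariate == "CONST", ]
  expect_true(all(const_rows$p_value == 1))
  expect_match(const_rows$note[1], "constant")
})

test_that("a candidate list of one yields a trivial ranking", {
  d <- synthetic_dataset(cohort_config(n = 30), final_model(), seed = 2)
  tab <- compare_structural(d, list(only = base_search_model()),
                            saem_control(80, 40), seed = 1,
                            n_samples = 300)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$dofv_vs_best, 0)
})

test_that("with a wide dose range the saturable-F model beats the
           constant-F model on data generated with saturation", {
  # equal numbers at each menu dose spanning 100-1200 mg maximise the
  # bioavailability contrast
  cfg <- cohort_config(n = 90,
                       dose_menu = c(`100` = 1/3, `300` = 1/3, `1200` = 1/3),
                       n_sample_probs = c(`1` = 0, `2` = 1))
  d <- synthetic_dataset(cfg, final_model(), seed = 8)
  cand <- default_candidates()[c("fo_saturable_F", "fo_constant_F")]
  tab <- compare_structural(d, cand, saem_control(150, 75), seed = 4,
                            n_samples = 600)
  expect_equal(tab$model[1], "fo_saturable_F")
  expect_gt(tab$ofv[tab$model == "fo_constant_F"] -
              tab$ofv[tab$model == "fo_saturable_F"], 3.84)
})

test_that("at a single dose level the two bioavailability models are
           statistically indistinguishable", {
  cfg <- cohort_config(n = 60, dose_menu = c(`300` = 1),
                       n_sample_probs = c(`1` = 0, `2` = 1))
  d <- synthetic_dataset(cfg, final_model(), seed = 10)
  cand <- default_candidates()[c("fo_saturable_F", "fo_constant_F")]
  tab <- compare_structural(d, cand, saem_control(150, 75), seed = 4,
                            n_samples = 600)
  expect_lt(abs(tab$ofv[1] - tab$ofv[2]), 3.84)
})

test_that("the staged search keeps an injected effect and stays empty
           under the null", {
  ctl <- saem_control(150, 75)
  # null truth: no covariate effects at all
  truth0 <- pop_model(init = c(V = 44.61, Cl = 5.73),
                      fixed = c(ka = 0.778, tlag = 0),
                      omega = c(V = 0.77, Cl = 0.28),
                      error = error_model("constant", a = 2.03))
  d0 <- synthetic_dataset(cohort_config(), truth0, seed = 21)
  s0 <- covariate_search(d0, ctl, n_samples = 400, seed = 1)
  expect_length(s0$final_model$covariate_effects, 0)

  d1 <- synthetic_dataset(cohort_config(), final_model(), seed = 5)
  s1 <- covariate_search(d1, ctl, n_samples = 400, seed = 1)
  covs <- vapply(s1$final_model$covariate_effects,
                 function(ce) paste(ce$covariate, ce$parameter), "")
  expect_true(any(covs %in% c("SCR Cl", "CRCL Cl", "EGFR Cl")))
  expect_true(all(c("stage", "covariate", "dofv", "decision") %in%
                    names(s1$trace)))
})

test_that("search results are reproducible under a fixed seed", {
  d <- synthetic_dataset(cohort_config(n = 40), final_model(), seed = 3)
  ctl <- saem_control(80, 40)
  stages <- list(list(label = "renal", parameter = "Cl",
                      covariates = c("SCR", "EGFR")))
  s1 <- covariate_search(d, ctl, stages = stages, n_samples = 300, seed = 9)
  s2 <- covariate_search(d, ctl, stages = stages, n_samples = 300, seed = 9)
  expect_identical(s1$trace, s2$trace)
  expect_identical(coef(s1$final_fit), coef(s2$final_fit))
})
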