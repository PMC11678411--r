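# helper: a fit object whose parameters are exactly the generating truth
# (no estimation), for diagnostics whose calibration is only defined when
# the model is correct
truth_fit <- function(dataset, truth = final_model(), seed = 1) {
  ctl <- saem_control(2, 2)
  fit <- fit_saem(dataset, truth, ctl, seed = seed)
  frame <- fit$frame
  fit$gamma <- frame$coef_init
  fit$omega <- frame$omega_init
  fit$err <- frame$error_init
  fit$ebe <- gabapk:::.ebe_laplace(fit)
  fit$estimates <- c()
  fit
}

test_that("the residual table has one calibrated row per observation", {
  d <- recovery_dataset(n = 60, seed = 14)
  fit <- truth_fit(d)
  rt <- pk_residuals(fit, nsim = 600, seed = 2)
  expect_equal(nrow(rt), n_observations(d))
  expect_true(all(is.finite(rt$iwres)))
  # data simulated from the evaluated model: weighted residuals are
  # standard normal up to Monte-Carlo error
  expect_lt(abs(mean(rt$iwres)), 0.15)
  expect_gt(sd(rt$pwres), 0.85); expect_lt(sd(rt$pwres), 1.15)
  expect_lt(abs(mean(rt$pwres)), 0.15)
  # IWRES definition: residual of one error SD gives IWRES 1
  a <- fit$err[["a"]]
  manual <- (rt$dv - rt$ipred) / a
  expect_equal(rt$iwres, manual)
})

test_that("VPC bands collapse onto the typical curve without variability
           and match the analytic quantiles with it", {
  # one common sampling time so each bin holds a single design point
  d <- recovery_dataset(n = 80, seed = 15, sample_offsets = 3)
  # degenerate: no random effects, (almost) no residual noise
  degen <- pop_model(init = c(V = 44.61, Cl = 5.73),
                     fixed = c(ka = 0.778, tlag = 0),
                     omega = c(), omega_fixed = c(V = 1e-6, Cl = 1e-6),
                     error = error_model("constant", a = 1e-6),
                     error_fixed = TRUE)
  fit0 <- truth_fit(d, degen)
  v0 <- vpc(fit0, n_rep = 100, bins = 3, seed = 5)
  typical <- conc_first_order(51, data.frame(time = seq(0, 48, 8),
                                             amount = 300),
                              structural_params(V = 44.61, Cl = 5.73,
                                                ka = 0.778))
  expect_equal(diff(range(v0$band$sim_median)), 0, tolerance = 1e-4)
  expect_equal(v0$band$sim_median, rep(typical, nrow(v0$band)),
               tolerance = 1e-4)
  expect_equal(v0$band$sim_upper - v0$band$sim_lower,
               rep(0, nrow(v0$band)), tolerance = 1e-4)

  # omega = 0 but a constant error: percentiles are f +/- 1.645 a
  noisy <- degen
  noisy$error <- error_model("constant", a = 2.03)
  fitn <- truth_fit(d, noisy)
  vn <- vpc(fitn, n_rep = 400, bins = 3, seed = 6)
  mid <- vn$band$sim_median[vn$band$percentile == 50]
  lo <- vn$band$sim_median[vn$band$percentile == 5]
  hi <- vn$band$sim_median[vn$band$percentile == 95]
  expect_equal(mid, typical, tolerance = 0.1)
  expect_equal(hi - mid, 1.645 * 2.03, tolerance = 0.15)
  expect_equal(mid - lo, 1.645 * 2.03, tolerance = 0.15)
})

test_that("about 90% of observations fall inside the 5th-95th simulated
           band when the model is true", {
  d <- recovery_dataset(n = 120, seed = 16)
  fit <- truth_fit(d)
  v <- vpc(fit, n_rep = 300, bins = 4, seed = 7)
  frame <- fit$frame
  inside <- 0; total <- 0
  # rebuild the same equal-count binning the VPC used and count the
  # observations inside the simulated 5th-95th band
  tt <- frame$obs_time
  qs <- stats::quantile(tt, probs = seq(0, 1, length.out = 5))
  bin <- cut(tt, unique(qs), include.lowest = TRUE)
  for (b in levels(bin)) {
    rows <- v$band[v$band$bin == b, ]
    if (!nrow(rows)) next
    lo <- rows$sim_median[rows$percentile == 5]
    hi <- rows$sim_median[rows$percentile == 95]
    y <- frame$y[bin == b]
    inside <- inside + sum(y >= lo & y <= hi)
    total <- total + length(y)
  }
  expect_gt(inside / total, 0.85)
  expect_lt(inside / total, 0.97)
})

test_that("VPC bands widen with more between-subject and residual
           variability", {
  d <- recovery_dataset(n = 60, seed = 17)
  width95 <- function(omega_v, a) {
    m <- pop_model(init = c(V = 44.61, Cl = 5.73),
                   fixed = c(ka = 0.778, tlag = 0),
                   omega = c(V = omega_v, Cl = 0.28),
                   error = error_model("constant", a = a))
    f <- truth_fit(d, m)
    v <- vpc(f, n_rep = 150, bins = 2, seed = 3)
    rows <- v$band[v$band$bin == v$band$bin[1], ]
    rows$sim_median[rows$percentile == 95] -
      rows$sim_median[rows$percentile == 5]
  }
  expect_gt(width95(1.2, 2.03), width95(0.77, 2.03))
  expect_gt(width95(0.77, 4), width95(0.77, 2.03))
})

test_that("sparse bins are merged into their neighbours", {
  d <- recovery_dataset(n = 10, seed = 18)  # 40 observations
  fit <- truth_fit(d)
  v <- vpc(fit, n_rep = 100, bins = 12, seed = 4)  # far too many bins
  expect_true(length(v$merged_bins) > 0)
  counts <- table(cut(fit$frame$obs_time,
                      unique(stats::quantile(fit$frame$obs_time,
                                             seq(0, 1, length.out = 13))),
                      include.lowest = TRUE))
  expect_true(any(counts < 5))  # the merge was actually needed
})

test_that("bootstrap is seed-reproducible and degenerate resampling
           returns the point estimates", {
  base <- pk_subject("X", data.frame(time = c(0, 8, 16), amount = 300),
                     data.frame(time = c(17, 19, 22, 24),
                                conc = c(4.1, 5.2, 3.9, 3.4)),
                     covariates = data.frame(SCR = 1.3))
  subs <- lapply(1:20, function(i) { s <- base; s$id <- paste0("X", i); s })
  d <- pk_dataset(subs)
  m <- pop_model(init = c(V = 45.4, Cl = 6.31),
                 fixed = c(ka = 0.778, tlag = 0),
                 omega = c(V = 0.3, Cl = 0.3),
                 error = error_model("constant", a = 1))
  ctl <- saem_control(60, 40)
  b1 <- pk_bootstrap(d, m, n_rep = 4, seed = 31, control = ctl)
  b2 <- pk_bootstrap(d, m, n_rep = 4, seed = 31, control = ctl)
  expect_identical(b1$resample_indices, b2$resample_indices)
  expect_identical(b1$estimates, b2$estimates)
  expect_false(b1$unstable)
  # identical subjects: every resample carries the same information
  point <- coef(fit_saem(d, m, ctl, seed = 32))
  for (p in c("V", "Cl")) {
    expect_lt(abs(b1$summary$median[b1$summary$parameter == p] - point[p]) /
                point[p], 0.1)
  }
  # percentile interval contains its median, structurally
  expect_true(all(b1$summary$lower <= b1$summary$median + 1e-12))
  expect_true(all(b1$summary$upper >= b1$summary$median - 1e-12))
})
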