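test_that("saturable bioavailability evaluates the published constants", {
  expect_equal(bioavailability(300), 823 / 1420)
  expect_equal(bioavailability(0), 823 / 1120)
  expect_equal(bioavailability(1120), bioavailability(0) / 2)
  expect_error(bioavailability(-1), "non-negative")
  doses <- seq(0, 2400, by = 100)
  expect_true(all(diff(bioavailability(doses)) < 0))
  expect_true(all(bioavailability(doses) <= 823 / 1120))
})

published_params <- function(...) {
  structural_params(V = 44.61, Cl = 5.73, ka = 0.778, ...)
}

test_that("single-dose concentration matches the frozen oracle value", {
  p <- published_params()
  one <- data.frame(time = 0, amount = 300)
  expect_equal(conc_first_order(0, one, p), 0)
  expect_equal(conc_first_order(3, one, p), 2.723, tolerance = 5e-4)
  # against the independent ODE integration at tight tolerance
  tt <- c(0.5, 1, 3, 8, 24)
  expect_rel_equal(conc_first_order(tt, one, p), ode_oracle_fo(tt, one, p),
                   1e-8)
})

test_that("superposition: multi-dose equals the sum of single doses", {
  p <- published_params()
  two <- data.frame(time = c(0, 8), amount = c(300, 300))
  expect_equal(conc_first_order(11, two, p), 3.859, tolerance = 5e-4)
  expect_equal(conc_first_order(11, two, p),
               conc_first_order(11, data.frame(time = 0, amount = 300), p) +
                 conc_first_order(3, data.frame(time = 0, amount = 300), p))
  expect_rel_equal(conc_first_order(c(2, 11, 30), two, p),
                   ode_oracle_fo(c(2, 11, 30), two, p), 1e-8)
})

test_that("closed form tracks the ODE oracle over random draws", {
  set.seed(11)
  for (i in 1:20) {
    p <- structural_params(V = runif(1, 20, 80), Cl = runif(1, 2, 12),
                           ka = runif(1, 0.3, 2),
                           tlag = sample(c(0, 0.31), 1))
    nd <- sample(1:5, 1)
    doses <- data.frame(time = c(0, sort(runif(nd - 1, 1, 40))),
                        amount = sample(c(100, 300, 600, 1200), nd,
                                        replace = TRUE))[seq_len(nd), ]
    tt <- sort(runif(4, 0.5, 60))
    expect_rel_equal(conc_first_order(tt, doses, p),
                     ode_oracle_fo(tt, doses, p), 1e-8)
  }
})

test_that("the ka = ke degeneracy switches to the analytic limit", {
  one <- data.frame(time = 0, amount = 300)
  ka <- 0.5
  p_eq <- structural_params(V = 40, Cl = 40 * ka, ka = ka)     # ke == ka
  p_near <- structural_params(V = 40, Cl = 40 * ka * (1 + 1e-7), ka = ka)
  expect_rel_equal(conc_first_order(c(1, 4, 10), one, p_eq),
                   conc_first_order(c(1, 4, 10), one, p_near), 1e-5)
  expect_rel_equal(conc_first_order(c(1, 4, 10), one, p_eq),
                   ode_oracle_fo(c(1, 4, 10), one, p_eq), 1e-6)
})

test_that("raising clearance lowers post-peak concentrations", {
  one <- data.frame(time = 0, amount = 300)
  lo <- structural_params(V = 44.61, Cl = 4, ka = 0.778)
  hi <- structural_params(V = 44.61, Cl = 8, ka = 0.778)
  tt <- seq(4, 48, by = 2)  # past the absorption peak
  expect_true(all(conc_first_order(tt, one, hi) <
                    conc_first_order(tt, one, lo)))
})

test_that("saturation makes exposure less than dose-proportional", {
  p <- published_params()
  tt <- seq(0.5, 24, by = 0.5)
  c300 <- conc_first_order(tt, data.frame(time = 0, amount = 300), p)
  c1200 <- conc_first_order(tt, data.frame(time = 0, amount = 1200), p)
  expect_true(all(c1200 / c300 < 4))
})

test_that("transit model: zero at t = 0 and mass balance into the centre", {
  p <- structural_params(V = 44.61, Cl = 5.73, ka = 1, n_transit = 1,
                         ktr = 1)
  one <- data.frame(time = 0, amount = 300)
  expect_equal(conc_transit(0, one, p), 0)
  # total drug ever eliminated = integral of Cl * C(t) = F * D
  got <- stats::integrate(function(t) conc_transit(t, one, p) * p$Cl,
                          0, Inf, rel.tol = 1e-9)$value
  expect_rel_equal(got, bioavailability(300) * 300, 1e-6)
})

test_that("transit closed form agrees with numeric ODE integration", {
  p <- structural_params(V = 44.61, Cl = 5.73, ka = 1, n_transit = 3,
                         ktr = 0.9)
  doses <- data.frame(time = c(0, 8), amount = c(300, 600))
  tt <- c(1, 3, 7, 12, 24)
  expect_rel_equal(conc_transit(tt, doses, p),
                   gabapk:::.conc_transit_ode(tt, doses, p), 1e-8)
  # slow-transit regime (ktr < ke) exercises the recursion branch
  p2 <- structural_params(V = 20, Cl = 10, ka = 1, n_transit = 2,
                          ktr = 0.3)
  expect_rel_equal(conc_transit(tt, doses, p2),
                   gabapk:::.conc_transit_ode(tt, doses, p2), 1e-6)
})

test_that("transit chain limits: n = 0 is first order; fast chain", {
  one <- data.frame(time = 0, amount = 300)
  tt <- seq(0.5, 24, by = 0.5)
  p0 <- structural_params(V = 44.61, Cl = 5.73, ka = 1, n_transit = 0,
                          ktr = 0.778)
  fo <- structural_params(V = 44.61, Cl = 5.73, ka = 0.778)
  expect_rel_equal(conc_transit(tt, one, p0), conc_first_order(tt, one, fo),
                   1e-10)
  # with a very fast chain the profile approaches first-order absorption
  # at the chain rate
  pfast <- structural_params(V = 44.61, Cl = 5.73, ka = 1, n_transit = 1,
                             ktr = 100 * 0.778)
  fofast <- structural_params(V = 44.61, Cl = 5.73, ka = 100 * 0.778)
  ref <- max(conc_first_order(tt, one, fofast))
  expect_lt(max(abs(conc_transit(tt, one, pfast) -
                      conc_first_order(tt, one, fofast))) / ref, 0.01)
})

test_that("steady-state closed form matches brute-force accumulation", {
  p <- published_params()
  long <- data.frame(time = seq(0, 8 * 199, by = 8),
                     amount = rep(300, 200))
  t_eval <- 8 * 199 + c(1, 3, 6, 8)
  expect_rel_equal(conc_steady_state(c(1, 3, 6, 8), 300, 8, p),
                   conc_first_order(t_eval, long, p), 1e-6)
})
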