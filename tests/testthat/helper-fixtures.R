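# shared fixture builders; everything is generated in code at test time

# a tiny hand-built dataset: two subjects, multi-dose histories
tiny_dataset <- function() {
  s1 <- pk_subject("A",
                   doses = data.frame(time = c(0, 8), amount = c(300, 300)),
                   observations = data.frame(time = c(3, 11),
                                             conc = c(2.7, 3.9)),
                   covariates = data.frame(AGE = 40, SEX = "male",
                                           RACE = "white", WT = 72, HT = 180,
                                           SCR = 1.0, FPG = 95, DM = FALSE))
  s2 <- pk_subject("B",
                   doses = data.frame(time = 0, amount = 600),
                   observations = data.frame(time = 5, conc = 4.1),
                   covariates = data.frame(AGE = 70, SEX = "female",
                                           RACE = "black", WT = 90, HT = 160,
                                           SCR = 2.1, FPG = 180, DM = TRUE))
  pk_dataset(list(s1, s2), provenance = "unit test fixture")
}

# rich-design dataset for estimation tests: n subjects, dense sampling
rich_dataset <- function(n = 30, truth = final_model(), seed = 1,
                         sample_times = c(1, 2, 4, 6, 8, 12, 16, 24)) {
  set.seed(seed)
  ln <- c(meanlog = log(1.3) - 0.465 / 2, sdlog = sqrt(0.465))
  scr <- pmin(pmax(exp(rnorm(n, ln[1], ln[2])), 0.4), 3.8)
  cohort <- data.frame(ID = sprintf("T%03d", seq_len(n)), SCR = scr)
  design <- lapply(seq_len(n), function(i) {
    list(id = cohort$ID[i],
         doses = data.frame(time = 0, amount = 300),
         sample_times = sample_times)
  })
  simulate_concentrations(design, cohort, truth, seed = seed + 1000)
}

# independent ODE oracle for the first-order oral model (deSolve)
ode_oracle_fo <- function(t, doses, params, rtol = 1e-12) {
  deriv <- function(t, y, parms) {
    list(c(-params$ka * y[1], params$ka * y[1] - params$ke * y[2]))
  }
  f <- if (is.null(params$dmax)) rep(1, nrow(doses)) else
    bioavailability(doses$amount, params$dmax, params$d50)
  ev <- data.frame(var = "gut", time = doses$time + params$tlag,
                   value = f * doses$amount, method = "add")
  times <- sort(unique(c(0, ev$time, t)))
  sol <- deSolve::lsoda(c(gut = 0, cen = 0), times, deriv, NULL,
                        rtol = rtol, atol = 1e-14, events = list(data = ev))
  unname(sol[match(t, sol[, 1]), "cen"] / params$V)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)), tol)
}
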