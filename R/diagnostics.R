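#' Goodness-of-fit residual table
#'
#' One row per observation with the population prediction, the individual
#' (empirical-Bayes) prediction, and the weighted residuals:
#' IWRES = (y - f(psi_i)) / g(f(psi_i)) with g the residual SD, and
#' PWRES = (y - E[y]) / SD[y] with the population moments obtained by
#' Monte-Carlo simulation of the random effects under the fitted model
#' (robust to the nonlinear bioavailability, unlike linearisation).
#'
#' @param fit a `saem_fit`
#' @param nsim random-effect draws for the population moments
#' @param seed RNG seed
#' @return data.frame: ID, time, dv, pred, ipred, pwres, iwres
#' @export
pk_residuals <- function(fit, nsim = 1000, seed = fit$seed + 2e6) {
  stopifnot(inherits(fit, "saem_fit"))
  frame <- fit$frame
  ipred <- .predict_phi(frame, fit$ebe$mode)
  iwres <- (frame$y - ipred) / .err_sd(ipred, fit$err, frame$error_kind)

  set.seed(seed)
  mu <- .frame_mu(frame, fit$gamma)
  sum_f <- numeric(frame$n_obs); sum_f2 <- numeric(frame$n_obs)
  sum_g2 <- numeric(frame$n_obs)
  for (s in seq_len(nsim)) {
    eta <- sweep(matrix(stats::rnorm(frame$n * frame$d), frame$n, frame$d),
                 2, fit$omega, `*`)
    preds <- .predict_phi(frame, mu + eta)
    sum_f <- sum_f + preds
    sum_f2 <- sum_f2 + preds^2
    sum_g2 <- sum_g2 + .err_sd(preds, fit$err, frame$error_kind)^2
  }
  epop <- sum_f / nsim
  vpop <- pmax(sum_f2 / nsim - epop^2, 0) + sum_g2 / nsim
  pwres <- (frame$y - epop) / sqrt(vpop)
  data.frame(ID = frame$ids[frame$isubj_obs], time = frame$obs_time,
             dv = frame$y, pred = epop, ipred = ipred,
             pwres = pwres, iwres = iwres)
}

#' Visual predictive check
#'
#' Simulates `n_rep` replicate datasets under the fitted model with the
#' original design (doses, sampling times, covariates), bins observations
#' by time since first dose (equal-count bins), and per bin compares the
#' empirical 5th/50th/95th percentiles of the observations with the
#' distribution of the same percentiles across the simulated replicates
#' (median and a 95\% confidence band). Bins holding fewer than 5
#' observations are merged with their neighbour.
#'
#' @param fit a `saem_fit`
#' @param n_rep simulation replicates (>= 100)
#' @param bins target number of time bins
#' @param seed RNG seed
#' @param pi percentiles to track
#' @param ci confidence level for the simulated percentile bands
#' @return a `pk_vpc` object (list of data.frames, `plot()`-able)
#' @export
vpc <- function(fit, n_rep = 500, bins = 6, seed = fit$seed + 3e6,
                pi = c(0.05, 0.5, 0.95), ci = 0.95) {
  stopifnot(inherits(fit, "saem_fit"), n_rep >= 100)
  frame <- fit$frame
  tt <- frame$obs_time
  edges <- unique(stats::quantile(tt, probs = seq(0, 1, length.out = bins + 1)))
  if (length(edges) < 2) edges <- c(edges - 0.5, edges + 0.5)
  bin <- cut(tt, edges, include.lowest = TRUE)
  merged <- character(0)
  while (any(table(bin) < 5) && nlevels(bin) > 1) {
    small <- which(table(bin) < 5)[1]
    j <- if (small == 1) 2 else small - 1
    merged <- c(merged, levels(bin)[small])
    lv <- levels(bin)
    lv[small] <- lv[j]
    levels(bin) <- lv
    bin <- droplevels(bin)
  }
  nb <- nlevels(bin)
  bin_mid <- as.numeric(tapply(tt, bin, stats::median))

  set.seed(seed)
  sim_q <- array(NA_real_, c(n_rep, nb, length(pi)))
  for (r in seq_len(n_rep)) {
    ysim <- .frame_simulate(frame, fit$gamma, fit$omega, fit$err)$y
    for (b in seq_len(nb)) {
      sim_q[r, b, ] <- stats::quantile(ysim[bin == levels(bin)[b]],
                                       probs = pi)
    }
  }
  alpha <- (1 - ci) / 2
  band <- do.call(rbind, lapply(seq_len(nb), function(b) {
    do.call(rbind, lapply(seq_along(pi), function(q) {
      data.frame(bin = levels(bin)[b], time = bin_mid[b],
                 percentile = 100 * pi[q],
                 sim_median = stats::median(sim_q[, b, q]),
                 sim_lower = stats::quantile(sim_q[, b, q], alpha),
                 sim_upper = stats::quantile(sim_q[, b, q], 1 - alpha))
    }))
  }))
  obs <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(bin = levels(bin)[b], time = bin_mid[b],
               percentile = 100 * pi,
               observed = as.numeric(
                 stats::quantile(frame$y[bin == levels(bin)[b]],
                                 probs = pi, names = FALSE)))
  }))
  row.names(band) <- row.names(obs) <- NULL
  structure(list(band = band, observed = obs,
                 points = data.frame(time = tt, dv = frame$y),
                 n_rep = n_rep, merged_bins = merged, pi = pi, ci = ci),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat("VPC:", x$n_rep, "replicates,", length(unique(x$band$bin)), "bins\n")
  if (length(x$merged_bins)) {
    cat("merged sparse bins:", paste(x$merged_bins, collapse = ", "), "\n")
  }
  print(x$band)
  invisible(x)
}

#' @rdname vpc
#' @param x a `pk_vpc` object
#' @param ... ignored
#' @export
plot.pk_vpc <- function(x, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = x$band,
                         ggplot2::aes(x = .data$time, ymin = .data$sim_lower,
                                      ymax = .data$sim_upper,
                                      group = .data$percentile),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(data = x$band,
                       ggplot2::aes(x = .data$time, y = .data$sim_median,
                                    group = .data$percentile)) +
    ggplot2::geom_line(data = x$observed,
                       ggplot2::aes(x = .data$time, y = .data$observed,
                                    group = .data$percentile),
                       linetype = 2, colour = "firebrick") +
    ggplot2::geom_point(data = x$points,
                        ggplot2::aes(x = .data$time, y = .data$dv),
                        colour = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "time since first dose (h)",
                  y = "concentration (ug/mL)",
                  title = "Visual predictive check")
}

#' Nonparametric bootstrap of a population model
#'
#' Resamples subjects with replacement to the original cohort size,
#' refits each replicate from the original initial values, and summarises
#' each parameter by its median and 2.5-97.5 percentile interval over the
#' converged replicates. Non-converged replicates are counted and
#' excluded; the result is flagged unstable when more than 20\% fail.
#'
#' @param dataset a [pk_dataset()]
#' @param model the model to refit (original initial values)
#' @param n_rep bootstrap replicates (the reference analysis used 1000;
#'   smaller values are appropriate at desk scale)
#' @param seed RNG seed (drives the resampling and the fits)
#' @param control a [saem_control()]
#' @return a `pk_bootstrap` object: `summary` data.frame, raw `estimates`,
#'   failure count and `unstable` flag
#' @export
pk_bootstrap <- function(dataset, model, n_rep = 200, seed = 1,
                         control = saem_control()) {
  stopifnot(n_rep >= 1)
  n <- length(dataset$subjects)
  set.seed(seed)
  idx_mat <- matrix(sample.int(n, n * n_rep, replace = TRUE), n_rep, n)
  ests <- vector("list", n_rep)
  failures <- 0L
  for (r in seq_len(n_rep)) {
    subs <- dataset$subjects[idx_mat[r, ]]
    for (j in seq_along(subs)) subs[[j]]$id <- paste0("bs", j)
    bs_data <- pk_dataset(subs, provenance = "bootstrap resample")
    ests[[r]] <- tryCatch(
      coef(fit_saem(bs_data, model, control, seed = seed + r)),
      error = function(e) { failures <<- failures + 1L; NULL })
  }
  est <- do.call(rbind, ests[!vapply(ests, is.null, TRUE)])
  if (is.null(est)) {
    stop_gabapk("all bootstrap replicates failed", class = "gabapk_numeric_error")
  }
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, stats::median),
    lower = apply(est, 2, stats::quantile, 0.025),
    upper = apply(est, 2, stats::quantile, 0.975),
    row.names = NULL)
  structure(list(summary = summ, estimates = est,
                 n_attempted = n_rep, n_converged = nrow(est),
                 unstable = failures > 0.2 * n_rep,
                 resample_indices = idx_mat),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat("bootstrap:", x$n_converged, "of", x$n_attempted,
      "replicates converged",
      if (x$unstable) "(UNSTABLE: >20% failures)" else "", "\n")
  print(x$summary)
  invisible(x)
}
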