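# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
stop_gabapk <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "gabapk_error")))
}

# truncated normal by rejection; bounds honoured exactly
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower > upper) stop_gabapk("impossible truncation: lower > upper",
                                 class = "gabapk_config_error")
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# log-normal truncated on the natural scale
rtrunclnorm <- function(n, meanlog, sdlog, lower, upper) {
  exp(rtruncnorm(n, meanlog, sdlog, log(lower), log(upper)))
}
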