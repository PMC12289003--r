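# Posterior summaries and convergence diagnostics.
#
# Split-chain R-hat and effective sample size follow the standard
# definitions: each chain is split in half, R-hat is the square root of the
# ratio of the pooled-variance estimate to the mean within-chain variance,
# and ESS uses chain-averaged autocovariances with Geyer's initial-positive-
# sequence truncation.

.split_chains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1):n, , drop = FALSE])
}

.rhat <- function(mat) {
  sm <- .split_chains(mat)
  n <- nrow(sm)
  if (n < 2L) return(NA_real_)
  w <- mean(apply(sm, 2, var))
  b_over_n <- var(colMeans(sm))
  if (w < 1e-12) return(1)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

.ess <- function(mat, max_lag = 100L) {
  sm <- .split_chains(mat)
  n <- nrow(sm); m <- ncol(sm)
  total <- n * m
  w <- mean(apply(sm, 2, var))
  if (n < 4L || w < 1e-12) return(total)
  var_plus <- (n - 1) / n * w + var(colMeans(sm))
  lag_max <- min(n - 1L, max_lag)
  acov <- vapply(seq_len(m), function(j)
    drop(acf(sm[, j], lag.max = lag_max, type = "covariance",
             plot = FALSE, demean = TRUE)$acf),
    numeric(lag_max + 1L))
  rho <- 1 - (w - rowMeans(acov)[-1]) / var_plus
  # Geyer initial positive sequence over paired lags
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  min(total, total / tau)
}

.chain_matrix <- function(draws, quantity) {
  chains <- sort(unique(draws$chain))
  vapply(chains, function(ch) draws[draws$chain == ch, quantity],
         numeric(sum(draws$chain == chains[1])))
}

#' Summarize posterior draws
#'
#' Posterior mean, equal-tailed credible interval (the `alpha/2` and
#' `1 - alpha/2` posterior quantiles of the pooled draws), split-chain R-hat
#' and effective sample size for the eight model parameters and the three
#' derived effects.
#'
#' @param fit a `mediation_fit` object (or a compatible draws data.frame
#'   with `chain` and quantity columns).
#' @param level credible level in (0, 1); default 0.95.
#' @return a data.frame of class `fit_summary` with columns
#'   `quantity, mean, ci_lower, ci_upper, rhat, ess`.
#' @export
summarize_draws <- function(fit, level = 0.95) {
  if (!is_scalar_num(level) || level <= 0 || level >= 1)
    pm_config_error("level must lie strictly between 0 and 1")
  draws <- if (inherits(fit, "mediation_fit")) fit$draws else fit
  quantities <- intersect(.quantity_names, names(draws))
  if (length(quantities) == 0L)
    pm_data_error("no recognized quantity columns in draws")
  if (nrow(draws) < 1000L)
    pm_data_error("need at least 1000 pooled draws for reported summaries")
  alpha <- (1 - level) / 2
  rows <- lapply(quantities, function(q) {
    v <- draws[[q]]
    qs <- unname(quantile(v, c(alpha, 1 - alpha), names = FALSE, type = 7))
    cm <- .chain_matrix(draws, q)
    data.frame(quantity = q, mean = mean(v),
               ci_lower = qs[1], ci_upper = qs[2],
               rhat = .rhat(cm), ess = .ess(cm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("fit_summary", "data.frame")
  out
}

#' Write a fit summary as CSV
#'
#' Header: `quantity,mean,ci_lower,ci_upper,rhat,ess`.
#'
#' @param summary a `fit_summary` data.frame.
#' @param path file path.
#' @export
write_fit_summary <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
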