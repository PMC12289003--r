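# Two-equation Bayesian mediation model, fitted by blocked Gibbs sampling.
#
# The mediator equation m ~ N(im + a*x, sigma_m^2) and the outcome equation
# y ~ N(iy + cprime*x + d*z + b*m, sigma_y^2) share no parameters and are
# conditionally independent given the data, so their Gibbs blocks are
# updated independently — an exactness property of this likelihood, not an
# approximation. With normal priors on coefficients and inverse-gamma priors
# on the residual variances every full conditional is available in closed
# form, so the sampler draws exact conditional samples (no tuning, no
# accept/reject step).

.quantity_names <- c("a", "b", "cprime", "d", "im", "iy",
                     "sigma_m", "sigma_y",
                     "direct_effect", "indirect_effect", "total_effect")

.metric_quantities <- setdiff(.quantity_names, "direct_effect")

.validate_analysis_table <- function(table) {
  req <- c("x", "z", "m", "y")
  if (!all(req %in% names(table)))
    pm_data_error(sprintf("analysis table must have columns %s",
                          paste(req, collapse = ", ")))
  if (nrow(table) < 5L)
    pm_data_error("mediation fit needs at least 5 subjects")
  vals <- as.matrix(table[, req])
  if (!all(is.finite(vals)))
    pm_data_error("analysis table contains non-finite values")
  if (length(unique(table$x)) < 2L)
    pm_data_error("degenerate design: only one treatment arm present")
  invisible(table)
}

.design_matrices <- function(table) {
  Xm <- cbind(intercept = 1, x = table$x)
  Xy <- cbind(intercept = 1, x = table$x, z = table$z, m = table$m)
  if (qr(Xy)$rank < ncol(Xy))
    pm_data_error("rank-deficient design: outcome predictors are collinear (is z or m constant?)")
  list(mediator = list(X = Xm, y = table$m, coefs = c("im", "a")),
       outcome = list(X = Xy, y = table$y, coefs = c("iy", "cprime", "d", "b")))
}

.data_fingerprint <- function(table) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(table[, c("x", "z", "m", "y")], tf)
  unname(tools::md5sum(tf))
}

#' Exact conjugate posterior for the regression coefficients
#'
#' With the residual variance held fixed, the coefficient posterior of each
#' equation is Gaussian in closed form:
#' `Sigma_n = (X'X / sigma2 + V0^-1)^-1`,
#' `mu_n = Sigma_n (X'y / sigma2 + V0^-1 mu_0)`, with independent
#' `Normal(coef_mean, coef_sd^2)` priors. This is the analytic oracle the
#' Gibbs sampler is tested against.
#'
#' @param table analysis table with columns `x, z, m, y`.
#' @param priors a [prior_spec()].
#' @param fixed_sigma2 named list/vector with elements `mediator` and
#'   `outcome`: the residual variances to condition on (> 0).
#' @return a list with elements `mediator` and `outcome`, each containing
#'   the posterior `mean` (named vector) and `cov` (matrix).
#' @export
closed_form_posterior <- function(table, priors = prior_spec(), fixed_sigma2) {
  .validate_analysis_table(table)
  fs <- as.list(fixed_sigma2)
  if (is.null(fs$mediator) || is.null(fs$outcome) ||
      fs$mediator <= 0 || fs$outcome <= 0)
    pm_config_error("fixed_sigma2 must supply positive 'mediator' and 'outcome' variances")
  eqs <- .design_matrices(table)
  out <- lapply(names(eqs), function(nm) {
    eq <- eqs[[nm]]
    p <- ncol(eq$X)
    prec0 <- rep(1 / priors$coef_sd^2, p)
    P <- crossprod(eq$X) / fs[[nm]] + diag(prec0, p)
    b <- crossprod(eq$X, eq$y) / fs[[nm]] + prec0 * priors$coef_mean
    covm <- solve(P)
    mu <- drop(covm %*% b)
    names(mu) <- eq$coefs
    dimnames(covm) <- list(eq$coefs, eq$coefs)
    list(mean = mu, cov = covm)
  })
  names(out) <- names(eqs)
  out
}

#' Fit the Bayesian mediation model by blocked Gibbs sampling
#'
#' Runs `n_chains` independent chains. Each chain is initialized at the OLS
#' point estimates jittered by `Normal(0, 0.5 * SE)` (overdispersed starts,
#' so R-hat is informative) and alternates exact draws from the coefficient
#' full conditional (multivariate normal) and the residual-variance full
#' conditional (inverse gamma) of each equation. Per retained draw the
#' derived effects are attached: `direct = cprime`, `indirect = a * b`,
#' `total = cprime + a * b`.
#'
#' @param table analysis table (see [extract_cohort()] /
#'   [simulate_ground_truth()]) with columns `x, z, m, y`.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param fixed_sigma2 optional named list/vector (`mediator`, `outcome`):
#'   hold the residual variances fixed at these values instead of sampling
#'   them (used to compare against [closed_form_posterior()]).
#' @return an object of class `mediation_fit` with element `draws`, a
#'   data.frame of one row per retained draw with columns `chain`,
#'   `iteration`, the eight parameters (`a, b, cprime, d, im, iy, sigma_m,
#'   sigma_y`) and the three derived effects.
#' @examples
#' cfg <- cohort_config(n_subjects = 40, seed = 3)
#' tab <- simulate_ground_truth(cfg)
#' fit <- fit_mediation(tab, mcmc = mcmc_config(n_chains = 2, n_draws = 500,
#'                                              n_burn_in = 200, seed = 1))
#' summarize_draws(fit)
#' @export
fit_mediation <- function(table, priors = prior_spec(), mcmc = mcmc_config(),
                          fixed_sigma2 = NULL) {
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_config"))
  .validate_analysis_table(table)
  eqs <- .design_matrices(table)
  fs <- if (is.null(fixed_sigma2)) list(mediator = -1, outcome = -1)
        else {
          fsl <- as.list(fixed_sigma2)
          if (is.null(fsl$mediator) || is.null(fsl$outcome) ||
              fsl$mediator <= 0 || fsl$outcome <= 0)
            pm_config_error("fixed_sigma2 must supply positive 'mediator' and 'outcome' variances")
          fsl
        }

  # OLS anchors for chain initialization
  ols <- lapply(eqs, function(eq) {
    qx <- qr(eq$X)
    beta <- qr.coef(qx, eq$y)
    resid <- eq$y - eq$X %*% beta
    df <- nrow(eq$X) - ncol(eq$X)
    s2 <- max(sum(resid^2) / max(df, 1L), 1e-12)
    se <- sqrt(diag(chol2inv(qr.R(qx))) * s2)
    list(beta = beta, se = se, s2 = s2)
  })

  chain_draws <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(mcmc$seed, ch))
    per_eq <- lapply(names(eqs), function(nm) {
      eq <- eqs[[nm]]
      o <- ols[[nm]]
      p <- ncol(eq$X)
      beta0 <- o$beta + rnorm(p, 0, 0.5 * o$se)
      sigma2_0 <- if (fs[[nm]] > 0) fs[[nm]] else o$s2 * exp(rnorm(1, 0, 0.5))
      res <- .gibbs_conjugate_lm(eq$X, eq$y,
                                 mu0 = rep(priors$coef_mean, p),
                                 prec0 = rep(1 / priors$coef_sd^2, p),
                                 shape0 = priors$sigma2_shape,
                                 scale0 = priors$sigma2_scale,
                                 n_burn = mcmc$n_burn_in,
                                 n_keep = mcmc$n_draws,
                                 beta = beta0, sigma2 = max(sigma2_0, 1e-12),
                                 fixed_sigma2 = fs[[nm]])
      colnames(res$beta) <- eq$coefs
      res
    })
    names(per_eq) <- names(eqs)
    df <- data.frame(chain = ch, iteration = seq_len(mcmc$n_draws),
                     a = per_eq$mediator$beta[, "a"],
                     b = per_eq$outcome$beta[, "b"],
                     cprime = per_eq$outcome$beta[, "cprime"],
                     d = per_eq$outcome$beta[, "d"],
                     im = per_eq$mediator$beta[, "im"],
                     iy = per_eq$outcome$beta[, "iy"],
                     sigma_m = sqrt(per_eq$mediator$sigma2),
                     sigma_y = sqrt(per_eq$outcome$sigma2))
    chain_draws[[ch]] <- df
  }
  draws <- do.call(rbind, chain_draws)
  fit <- structure(list(draws = draws, n_chains = mcmc$n_chains,
                        n_draws = mcmc$n_draws, n_obs = nrow(table),
                        priors = priors, mcmc = mcmc,
                        data_hash = .data_fingerprint(table)),
                   class = "mediation_fit")
  derive_effects(fit)
}

#' Attach the derived mediation effects to posterior draws
#'
#' Per draw: `direct_effect = cprime`, `indirect_effect = a * b`,
#' `total_effect = cprime + a * b`. These identities hold exactly for every
#' retained draw, so posterior summaries of the effects propagate the joint
#' parameter uncertainty.
#'
#' @param fit a `mediation_fit` object, or a data.frame of draws with
#'   columns `a`, `b`, `cprime`.
#' @return the input with `direct_effect`, `indirect_effect` and
#'   `total_effect` columns added/overwritten.
#' @export
derive_effects <- function(fit) {
  df <- if (inherits(fit, "mediation_fit")) fit$draws else fit
  if (!all(c("a", "b", "cprime") %in% names(df)))
    pm_data_error("draws must contain columns a, b and cprime")
  df$direct_effect <- df$cprime
  df$indirect_effect <- df$a * df$b
  df$total_effect <- df$cprime + df$a * df$b
  if (inherits(fit, "mediation_fit")) {
    fit$draws <- df
    fit
  } else df
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Bayesian mediation fit: %d chains x %d draws, n = %d subjects\n",
              x$n_chains, x$n_draws, x$n_obs))
  print(summarize_draws(x), ...)
  invisible(x)
}
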