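#' Mediation model parameters
#'
#' The full parameter vector of the two-equation linear-Gaussian mediation
#' model. The mediator equation is `M_i ~ Normal(i_m + a * X_i, sigma_m)` and
#' the outcome equation is
#' `Y_i ~ Normal(i_y + c_prime * X_i + d * Z_i + b * M_i, sigma_y)`, where
#' `X` is the randomized treatment indicator, `M` the adverse-event severity
#' (mediator), `Z` the stress severity (covariate) and `Y` the fatigue
#' severity (outcome). All severities are continuous, unclipped values on a
#' nominal 0-10 scale.
#'
#' Defaults are the package's reference regime: moderate, detectable effects
#' at trial-scale cohorts of 75 subjects.
#'
#' @param a effect of treatment on the mediator (severity units per arm).
#' @param b effect of the mediator on the outcome.
#' @param c_prime direct effect of treatment on the outcome.
#' @param d effect of the stress covariate on the outcome.
#' @param i_m mediator intercept.
#' @param i_y outcome intercept.
#' @param sigma_m mediator residual SD (> 0).
#' @param sigma_y outcome residual SD (> 0).
#' @return an object of class `mediation_params`.
#' @examples
#' p <- mediation_params(a = 0.4, b = 0.5, c_prime = 0.3)
#' true_value_of(p, "indirect_effect") # 0.2
#' @export
mediation_params <- function(a = 0.4, b = 0.5, c_prime = 0.3, d = 0.2,
                             i_m = 1.0, i_y = 2.0,
                             sigma_m = 0.5, sigma_y = 0.5) {
  p <- list(a = a, b = b, c_prime = c_prime, d = d,
            i_m = i_m, i_y = i_y, sigma_m = sigma_m, sigma_y = sigma_y)
  for (nm in names(p)) {
    if (!is_scalar_num(p[[nm]]))
      pm_config_error(sprintf("mediation parameter '%s' must be a finite number", nm))
  }
  if (sigma_m < 0 || sigma_y < 0)
    pm_config_error("sigma_m and sigma_y must be non-negative")
  structure(p, class = "mediation_params")
}

#' Cohort simulation configuration
#'
#' Settings for one simulated trial cohort: sample size, the true mediation
#' parameters, the stress-covariate distribution, the fatigue yes/no
#' branching threshold, and how severities are rounded when rendered into
#' dialogue text. `sigma` parameters of zero are allowed (noiseless cohorts
#' for testing) but such cohorts cannot be fitted.
#'
#' @param n_subjects cohort size (>= 4, so each arm has at least 2 subjects).
#' @param params a [mediation_params()] object (the DGP truth).
#' @param z_mean,z_sd location and scale of the Normal stress covariate
#'   (defaults 5 and 2, mid-scale with realistic spread; `z_sd >= 0`).
#' @param fatigue_threshold fatigue severity at or above which the simulated
#'   patient answers "Yes" to the fatigue question (default 3).
#' @param render_precision decimal places used when severities are written
#'   into transcript text (>= 1).
#' @param seed cohort master seed; per-subject streams are derived with
#'   [derive_seed()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 75, params = mediation_params(),
                          z_mean = 5, z_sd = 2, fatigue_threshold = 3,
                          render_precision = 2, seed = 1) {
  if (!is_count(n_subjects, min = 4L))
    pm_config_error("n_subjects must be an integer >= 4 (two subjects per arm)")
  if (!inherits(params, "mediation_params")) params <- do.call(mediation_params, as.list(params))
  if (!is_scalar_num(z_mean) || !is_scalar_num(z_sd) || z_sd < 0)
    pm_config_error("z_mean must be finite and z_sd non-negative")
  if (!is_scalar_num(fatigue_threshold))
    pm_config_error("fatigue_threshold must be a finite number")
  if (!is_count(render_precision, min = 1L))
    pm_config_error("render_precision must be an integer >= 1")
  if (!is_count(seed, min = 0L))
    pm_config_error("seed must be a non-negative integer")
  structure(list(n_subjects = as.integer(n_subjects), params = params,
                 z_mean = z_mean, z_sd = z_sd,
                 fatigue_threshold = fatigue_threshold,
                 render_precision = as.integer(render_precision),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Prior specification for the mediation model
#'
#' Weakly informative conjugate priors: independent
#' `Normal(coef_mean, coef_sd^2)` priors on every regression coefficient and
#' intercept, and `InverseGamma(sigma2_shape, sigma2_scale)` priors on both
#' residual variances. The defaults (`Normal(0, 10^2)`,
#' `InverseGamma(0.001, 0.001)`) are flat relative to severity-scale effects
#' and keep the Gibbs sampler exact.
#'
#' @param coef_mean prior mean for each coefficient (default 0).
#' @param coef_sd prior SD for each coefficient (default 10, > 0).
#' @param sigma2_shape,sigma2_scale inverse-gamma hyperparameters for the
#'   residual variances (both > 0, default 0.001).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(coef_mean = 0, coef_sd = 10,
                       sigma2_shape = 0.001, sigma2_scale = 0.001) {
  if (!is_scalar_num(coef_mean)) pm_config_error("coef_mean must be finite")
  if (!is_scalar_num(coef_sd) || coef_sd <= 0) pm_config_error("coef_sd must be > 0")
  if (!is_scalar_num(sigma2_shape) || sigma2_shape <= 0)
    pm_config_error("sigma2_shape must be > 0")
  if (!is_scalar_num(sigma2_scale) || sigma2_scale <= 0)
    pm_config_error("sigma2_scale must be > 0")
  structure(list(coef_mean = coef_mean, coef_sd = coef_sd,
                 sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' @param n_chains number of independent chains (>= 2 so split-chain R-hat is
#'   informative; default 4).
#' @param n_draws retained post-burn-in draws per chain (>= 500; default 2000).
#' @param n_burn_in discarded initial draws per chain (default 1000).
#' @param seed sampler seed; per-chain streams derived with [derive_seed()].
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_draws = 2000, n_burn_in = 1000,
                        seed = 1) {
  if (!is_count(n_chains, min = 2L)) pm_config_error("n_chains must be an integer >= 2")
  if (!is_count(n_draws, min = 500L))
    pm_config_error("n_draws must be >= 500 per chain for reported summaries")
  if (!is_count(n_burn_in, min = 0L)) pm_config_error("n_burn_in must be a non-negative integer")
  if (!is_count(seed, min = 0L)) pm_config_error("seed must be a non-negative integer")
  structure(list(n_chains = as.integer(n_chains), n_draws = as.integer(n_draws),
                 n_burn_in = as.integer(n_burn_in), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Simulation study configuration
#'
#' @param n_replications number of independent replications (>= 2; 100 for
#'   the reference study).
#' @param cohort a [cohort_config()]; its `seed` field is overridden per
#'   replication by `master_seed + r`.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()]; its seed is likewise re-derived per
#'   replication.
#' @param use_transcript_path if `TRUE` (default) each cohort is rendered to
#'   transcripts and parsed back before fitting — the full pipeline; if
#'   `FALSE` the ground-truth table is fitted directly (fast path).
#' @param master_seed study master seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_replications = 100, cohort = cohort_config(),
                         priors = prior_spec(), mcmc = mcmc_config(),
                         use_transcript_path = TRUE, master_seed = 20240101) {
  if (!is_count(n_replications, min = 2L))
    pm_config_error("n_replications must be an integer >= 2")
  stopifnot(inherits(cohort, "cohort_config"), inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  if (!is.logical(use_transcript_path) || length(use_transcript_path) != 1L)
    pm_config_error("use_transcript_path must be TRUE or FALSE")
  if (!is_count(master_seed, min = 0L))
    pm_config_error("master_seed must be a non-negative integer")
  structure(list(n_replications = as.integer(n_replications), cohort = cohort,
                 priors = priors, mcmc = mcmc,
                 use_transcript_path = use_transcript_path,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}
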