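# The conjugate Gibbs sampler, its closed-form oracle, and posterior
# summaries.

test_that("closed-form posterior reduces to OLS and to the prior in the limits", {
  tab <- simulate_ground_truth(small_cohort(n = 60, seed = 41))
  flat <- closed_form_posterior(tab, prior_spec(coef_sd = 1e5),
                                fixed_sigma2 = list(mediator = 0.25, outcome = 0.25))
  ols_m <- coef(lm(m ~ x, data = tab))
  ols_y <- coef(lm(y ~ x + z + m, data = tab))
  expect_equal(unname(flat$mediator$mean), unname(ols_m), tolerance = 1e-5)
  expect_equal(unname(flat$outcome$mean), unname(ols_y), tolerance = 1e-5)

  tight <- closed_form_posterior(tab, prior_spec(coef_mean = 0.7, coef_sd = 1e-5),
                                 fixed_sigma2 = list(mediator = 0.25, outcome = 0.25))
  expect_equal(unname(tight$outcome$mean), rep(0.7, 4), tolerance = 1e-4)
})

test_that("closed-form posterior mean maximizes the log posterior density", {
  tab <- simulate_ground_truth(small_cohort(n = 25, seed = 43))
  pr <- prior_spec(coef_sd = 2)
  s2 <- 0.3
  cf <- closed_form_posterior(tab, pr, fixed_sigma2 = list(mediator = s2, outcome = s2))
  X <- cbind(1, tab$x, tab$z, tab$m)
  neg_log_post <- function(beta) {
    sum((tab$y - X %*% beta)^2) / (2 * s2) + sum(beta^2) / (2 * pr$coef_sd^2)
  }
  opt <- optim(rep(0, 4), neg_log_post, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(cf$outcome$mean), opt$par, tolerance = 1e-5)
})

test_that("with fixed residual variances the Gibbs posterior matches the oracle", {
  # deep 20-dataset sweep lives in the acceptance suite; spot-check here
  for (seed in c(51, 52)) {
    cfg <- small_cohort(n = 40, seed = seed)
    tab <- simulate_ground_truth(cfg)
    fs <- list(mediator = cfg$params$sigma_m^2, outcome = cfg$params$sigma_y^2)
    cf <- closed_form_posterior(tab, prior_spec(), fs)
    fit <- fit_mediation(tab, mcmc = quick_mcmc(seed = seed, n_draws = 1000),
                         fixed_sigma2 = fs)
    n_total <- 2 * 1000
    means <- colMeans(fit$draws[, c("im", "a", "iy", "cprime", "d", "b")])
    cf_mean <- c(cf$mediator$mean, cf$outcome$mean)
    cf_sd <- sqrt(c(diag(cf$mediator$cov), diag(cf$outcome$cov)))
    expect_true(all(abs(means - cf_mean) < 3 * cf_sd / sqrt(n_total)))
    expect_true(all(abs(fit$draws$sigma_m - sqrt(fs$mediator)) < 1e-12))
  }
})

test_that("nearly noiseless data pins the posterior to the truth", {
  # b and cprime are separated only by within-arm variation of m, so their
  # posterior SD scales with (sigma_y / sigma_m) / sqrt(n); the noiseless
  # limit pins every coefficient when the outcome noise vanishes faster
  # than the mediator noise.
  p <- mediation_params(sigma_m = 0.05, sigma_y = 1e-4)
  tab <- simulate_ground_truth(cohort_config(n_subjects = 200, params = p,
                                             seed = 47))
  fit <- fit_mediation(tab, mcmc = quick_mcmc(seed = 2))
  s <- summarize_draws(fit)
  est <- setNames(s$mean, s$quantity)
  expect_lt(abs(est[["a"]] - p$a), 0.02)
  expect_lt(abs(est[["b"]] - p$b), 0.02)
  expect_lt(abs(est[["cprime"]] - p$c_prime), 0.02)
})

test_that("derived effect identities hold exactly for every draw", {
  expect_equal(derive_effects(data.frame(a = 0, b = 5, cprime = 1.2)),
               data.frame(a = 0, b = 5, cprime = 1.2, direct_effect = 1.2,
                          indirect_effect = 0, total_effect = 1.2))
  d <- derive_effects(data.frame(a = 0.4, b = 0.5, cprime = 0.3))
  expect_identical(d$indirect_effect, 0.2)
  expect_identical(d$total_effect, 0.5)

  fit <- fit_mediation(simulate_ground_truth(small_cohort(seed = 40)),
                       mcmc = quick_mcmc(seed = 3))
  dr <- fit$draws
  expect_identical(dr$direct_effect, dr$cprime)
  expect_identical(dr$indirect_effect, dr$a * dr$b)
  expect_identical(dr$total_effect, dr$cprime + dr$a * dr$b)
  expect_identical(mean(dr$total_effect),
                   mean(dr$direct_effect + dr$indirect_effect))
  expect_true(all(dr$sigma_m > 0) && all(dr$sigma_y > 0))
})

test_that("summaries handle degenerate, Gaussian and non-mixing draws", {
  const <- fake_draws(list(rep(2, 600), rep(2, 600)))
  s <- summarize_draws(const)
  a_row <- s[s$quantity == "a", ]
  expect_equal(a_row$mean, 2)
  expect_equal(c(a_row$ci_lower, a_row$ci_upper), c(2, 2))
  expect_equal(a_row$rhat, 1)

  set.seed(99)
  z <- rnorm(10000)
  gauss <- fake_draws(split(z, rep(1:4, each = 2500)))
  g_row <- summarize_draws(gauss)[1, ]
  expect_lt(abs(g_row$ci_lower - (-1.96)), 0.08)
  expect_lt(abs(g_row$ci_upper - 1.96), 0.08)

  set.seed(100)
  disjoint <- fake_draws(list(rnorm(600, 0, 0.1), rnorm(600, 10, 0.1)))
  expect_gt(summarize_draws(disjoint)$rhat[1], 1.05)

  expect_error(summarize_draws(const, level = 1.2), class = "pm_config_error")
  expect_error(summarize_draws(fake_draws(list(rnorm(100), rnorm(100)))),
               class = "pm_data_error") # < 1000 pooled draws
})

test_that("sampling is reproducible and chains actually mix on real data", {
  tab <- simulate_ground_truth(small_cohort(n = 75, seed = 44))
  f1 <- fit_mediation(tab, mcmc = quick_mcmc(seed = 5))
  f2 <- fit_mediation(tab, mcmc = quick_mcmc(seed = 5))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$data_hash, f2$data_hash)
  s <- summarize_draws(f1)
  expect_true(all(s$rhat < 1.01))
  expect_true(all(s$ess > 100))
  expect_true(all(s$ci_lower < s$ci_upper))
  f3 <- fit_mediation(tab, mcmc = quick_mcmc(seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior means are insensitive to widening the weak prior", {
  tab <- simulate_ground_truth(cohort_config(n_subjects = 75, seed = 46))
  m10 <- summarize_draws(fit_mediation(tab, prior_spec(coef_sd = 10),
                                       mcmc = quick_mcmc(seed = 7)))
  m100 <- summarize_draws(fit_mediation(tab, prior_spec(coef_sd = 100),
                                        mcmc = quick_mcmc(seed = 7)))
  for (q in c("a", "b", "cprime", "d", "im", "iy")) {
    v10 <- m10$mean[m10$quantity == q]
    v100 <- m100$mean[m100$quantity == q]
    expect_lt(abs(v100 - v10) / abs(v10), 0.10)
  }
})

test_that("posterior error shrinks as the cohort grows", {
  sizes <- c(75, 500, 5000)
  seeds <- 61:65
  err <- sapply(sizes, function(n) {
    per_seed <- sapply(seeds, function(s) {
      tab <- simulate_ground_truth(cohort_config(n_subjects = n, seed = s))
      fit <- fit_mediation(tab, mcmc = quick_mcmc(seed = s))
      s8 <- summarize_draws(fit)
      est <- setNames(s8$mean, s8$quantity)
      p <- mediation_params()
      vapply(c("a", "b", "cprime", "d", "im", "iy", "sigma_m", "sigma_y"),
             function(q) abs(est[[q]] - true_value_of(p, q)), numeric(1))
    })
    rowMeans(per_seed)
  })
  for (i in seq_len(nrow(err))) {
    expect_lt(err[i, 2], err[i, 1])
    expect_lt(err[i, 3], err[i, 2])
  }
})

test_that("degenerate designs are rejected with typed errors", {
  tab <- simulate_ground_truth(small_cohort(n = 20, seed = 48))
  one_arm <- tab; one_arm$x <- 1L
  expect_error(fit_mediation(one_arm), "one treatment arm",
               class = "pm_data_error")
  flat_z <- tab; flat_z$z <- 5
  expect_error(fit_mediation(flat_z), "rank-deficient",
               class = "pm_data_error")
  expect_error(fit_mediation(tab[1:4, ]), class = "pm_data_error")
  bad <- tab; bad$m[3] <- NA
  expect_error(fit_mediation(bad), class = "pm_data_error")
  expect_error(mcmc_config(n_draws = 100), class = "pm_config_error")
})
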