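# Replicated simulation study: simulate -> (render -> extract) -> fit ->
# summarize, scored against the known DGP truth with the four estimator
# metrics (bias, RMSE, coverage, mean credible-interval width).

#' True value of a reported quantity under a parameter vector
#'
#' Returns the parameter itself for the eight primitives, `a * b` for the
#' indirect effect, `cprime` for the direct effect, and `cprime + a * b`
#' for the total effect.
#'
#' @param params a [mediation_params()] object.
#' @param quantity one of `a, b, cprime, d, im, iy, sigma_m, sigma_y,
#'   direct_effect, indirect_effect, total_effect`.
#' @return a number.
#' @export
true_value_of <- function(params, quantity) {
  stopifnot(inherits(params, "mediation_params"))
  switch(quantity,
         a = params$a, b = params$b, cprime = params$c_prime, d = params$d,
         im = params$i_m, iy = params$i_y,
         sigma_m = params$sigma_m, sigma_y = params$sigma_y,
         direct_effect = params$c_prime,
         indirect_effect = params$a * params$b,
         total_effect = params$c_prime + params$a * params$b,
         pm_config_error(sprintf("unknown quantity: %s", quantity)))
}

#' Compute the estimator-quality metrics over replications
#'
#' Per quantity with true value `g`, per-replication posterior mean `g_r`
#' and credible interval `[l_r, u_r]`:
#' bias `= mean(g_r - g)`, RMSE `= sqrt(mean((g_r - g)^2))`,
#' coverage `= mean(l_r <= g & g <= u_r)`, interval width
#' `= mean(u_r - l_r)`. Only converged replications enter the metrics; the
#' excluded count is attached as attribute `n_excluded` and must be
#' reported alongside the table.
#'
#' @param truths named numeric vector of true values, one per metric
#'   quantity (see [true_value_of()]).
#' @param results list of replication results as produced by [run_study()]:
#'   each a list with `replication_id`, `summary` (a `fit_summary`) and
#'   `converged` flag.
#' @return a data.frame of class `metrics_table` with columns
#'   `quantity, bias, rmse, coverage, interval_width` (10 rows), attribute
#'   `n_excluded`.
#' @export
compute_metrics <- function(truths, results) {
  if (length(results) < 2L)
    pm_data_error("compute_metrics() needs at least 2 replications")
  converged <- Filter(function(r) isTRUE(r$converged), results)
  if (length(converged) < 2L)
    pm_convergence_error(sprintf(
      "study failure: only %d of %d replications converged",
      length(converged), length(results)))
  quantities <- .metric_quantities
  missing <- setdiff(quantities, names(truths))
  if (length(missing) > 0L)
    pm_config_error(sprintf("truths missing quantities: %s",
                            paste(missing, collapse = ", ")))
  rows <- lapply(quantities, function(q) {
    g <- truths[[q]]
    est <- vapply(converged, function(r) {
      s <- r$summary[r$summary$quantity == q, ]
      c(s$mean, s$ci_lower, s$ci_upper)
    }, numeric(3))
    dev <- est[1, ] - g
    data.frame(quantity = q,
               bias = mean(dev),
               rmse = sqrt(mean(dev^2)),
               coverage = mean(est[2, ] <= g & g <= est[3, ]),
               interval_width = mean(est[3, ] - est[2, ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- length(results) - length(converged)
  attr(out, "n_replications") <- length(results)
  class(out) <- c("metrics_table", "data.frame")
  out
}

.replication_seed <- function(master_seed, r) {
  as.integer((as.double(master_seed) + r) %% 2147483647)
}

#' Run a replicated mediation simulation study
#'
#' For each replication `r` of `n_replications`: derive the replication
#' seed `master_seed + r`; simulate a cohort from the configured DGP;
#' either render the cohort to transcripts and extract the analysis table
#' back (full pipeline) or use the ground truth directly (fast path); fit
#' the mediation model; summarize; flag convergence (all split-chain R-hat
#' < 1.01). Finally score all converged replications against the configured
#' truth.
#'
#' @param config a [study_config()].
#' @param progress if `TRUE`, print one line per replication.
#' @return a list of class `study_result` with elements `metrics` (a
#'   `metrics_table`), `replications` (list of per-replication results:
#'   `replication_id`, `seed`, `summary`, `converged`) and `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  truths <- vapply(.metric_quantities, function(q)
    true_value_of(config$cohort$params, q), numeric(1))
  results <- vector("list", config$n_replications)
  for (r in seq_len(config$n_replications)) {
    seed_r <- .replication_seed(config$master_seed, r)
    res <- tryCatch({
      cohort_cfg <- config$cohort
      cohort_cfg$seed <- seed_r
      table <- if (config$use_transcript_path) {
        sim <- simulate_cohort(cohort_cfg)
        extract_cohort(sim$transcripts)
      } else {
        simulate_ground_truth(cohort_cfg)
      }
      mc <- config$mcmc
      mc$seed <- derive_seed(seed_r, 900001L)
      fit <- fit_mediation(table, priors = config$priors, mcmc = mc)
      summ <- summarize_draws(fit)
      list(replication_id = r, seed = seed_r, summary = summ,
           converged = all(is.finite(summ$rhat)) && all(summ$rhat < 1.01))
    }, promediate_error = function(e) {
      pm_stop(sprintf("replication %d (seed %d) failed: %s",
                      r, seed_r, conditionMessage(e)),
              class(e)[1])
    })
    if (progress)
      message(sprintf("replication %d/%d (seed %d): %s", r,
                      config$n_replications, seed_r,
                      if (res$converged) "converged" else "NOT converged"))
    results[[r]] <- res
  }
  metrics <- compute_metrics(truths, results)
  structure(list(metrics = metrics, replications = results, config = config),
            class = "study_result")
}

#' Write study outputs as CSV
#'
#' `write_metrics_table()` writes the 10-row metrics table
#' (`quantity,bias,rmse,coverage,interval_width`);
#' `write_replications()` writes one row per replication and quantity
#' (`replication_id,seed,quantity,post_mean,ci_lower,ci_upper,rhat,converged`).
#'
#' @param study a `study_result` (or, for `write_metrics_table()`, a
#'   `metrics_table`).
#' @param path file path.
#' @export
write_metrics_table <- function(study, path) {
  metrics <- if (inherits(study, "study_result")) study$metrics else study
  write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
write_replications <- function(study, path) {
  stopifnot(inherits(study, "study_result"))
  rows <- lapply(study$replications, function(r) {
    s <- as.data.frame(r$summary)
    data.frame(replication_id = r$replication_id, seed = r$seed,
               quantity = s$quantity, post_mean = s$mean,
               ci_lower = s$ci_lower, ci_upper = s$ci_upper,
               rhat = s$rhat, converged = r$converged,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.study_result <- function(x, ...) {
  n_ex <- attr(x$metrics, "n_excluded")
  cat(sprintf("Mediation simulation study: %d replications (%d excluded as non-converged)\n",
              x$config$n_replications, n_ex))
  print(as.data.frame(x$metrics), row.names = FALSE, ...)
  invisible(x)
}
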