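# Internal helpers: error conditions and seed-stream derivation.

pm_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "promediate_error"),
                      call = call))
}

pm_config_error <- function(message) pm_stop(message, "pm_config_error")
pm_data_error <- function(message) pm_stop(message, "pm_data_error")
pm_parse_error <- function(message) pm_stop(message, "pm_parse_error")
pm_convergence_error <- function(message) pm_stop(message, "pm_convergence_error")

#' Derive a child RNG seed from a master seed and a stream index
#'
#' Deterministic multiplicative-hash scheme: each logical stream (a subject,
#' a chain, a sampler) gets its own seed so that enlarging a cohort never
#' perturbs the random numbers of earlier subjects. Result is kept inside
#' the signed 32-bit range `set.seed()` accepts.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master) %% m) * 48271 + as.double(stream) * 69621
  as.integer(s %% (m - 1) + 1)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
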