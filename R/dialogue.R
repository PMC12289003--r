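# Synthetic cohort generation and transcript rendering.
#
# Router (conversation flow): GREETING -> FATIGUE_YN -> FATIGUE_SEVERITY ->
# STRESS -> SIDE_EFFECTS. The fatigue yes/no answer branches the *wording*
# of the stress probe (stress as a cause of the reported fatigue vs. a
# general stress check); both branches elicit numeric zero-anchored
# severities for fatigue, stress and side effects so every subject yields a
# complete (Y, Z, M) triple.

.severity_nodes <- c(y = "FATIGUE_SEVERITY", z = "STRESS", m = "SIDE_EFFECTS")

# Template bank: >= 3 surface variants per (node, role). Severity user
# templates contain exactly one %s placeholder and no digits; non-severity
# user turns contain no digits at all, so the parser's uniqueness invariant
# holds by construction.
.template_bank <- list(
  GREETING = list(
    agent = c(
      "Hello! This is your study check-in assistant. How are you feeling today?",
      "Hi there, thanks for checking in. How have you been feeling?",
      "Good day! I'm here to ask a few questions about how you are doing."),
    user = c(
      "Hi, I'm doing alright overall, thanks for asking.",
      "Hello. Things have been up and down, but I'm managing.",
      "Hey there. I'm okay today, happy to answer your questions.")),
  FATIGUE_YN = list(
    agent = c(
      "Have you experienced fatigue recently?",
      "Let me ask first: have you been feeling fatigued?",
      "To start, have you noticed any fatigue since your last visit?"),
    user_yes = c(
      "Yes, I have been feeling quite fatigued lately.",
      "Yes, the tiredness has definitely been noticeable.",
      "Yes, I would say the fatigue has been bothering me."),
    user_no = c(
      "No, I haven't really felt fatigued.",
      "No, my energy has been fine overall.",
      "No, I can't say fatigue has been a problem.")),
  FATIGUE_SEVERITY = list(
    agent = c(
      "On a severity scale anchored at zero for no fatigue at all, how would you rate your fatigue?",
      "Using a scale where zero means no fatigue, what number best describes your fatigue right now?",
      "If zero means no fatigue whatsoever, how severe would you say your fatigue is?"),
    user = c(
      "I'd put my fatigue at about %s.",
      "Honestly, my fatigue feels like a %s.",
      "I would rate the fatigue around %s.")),
  STRESS = list(
    agent_yes = c(
      "Fatigue can have social or cultural causes. Thinking about stress at home or work, with zero meaning no stress, how severe is your stress?",
      "Sometimes stress contributes to fatigue. On a scale anchored at zero for none, how much social or cultural stress are you under?",
      "Could stress be playing a part in your fatigue? With zero meaning no stress at all, how severe is it?"),
    agent_no = c(
      "Even without fatigue, stress matters. With zero meaning no stress, how much social or cultural stress have you felt?",
      "Good to hear. Separately, on a scale anchored at zero for none, how severe has any social or cultural stress been?",
      "Thanks. I'd still like to ask about stress: with zero meaning none, how severe is the stress in your life right now?"),
    user = c(
      "My stress level is around %s these days.",
      "I'd say the stress sits near %s.",
      "Stress-wise, I'm at about %s.")),
  SIDE_EFFECTS = list(
    agent = c(
      "Finally, have you noticed side effects from the treatment? With zero meaning none, how severe are they?",
      "Lastly, thinking of any adverse effects of the treatment, with zero for none, how severe have they been?",
      "One more question: rating any treatment side effects on a scale anchored at zero for none, how severe are they?"),
    user = c(
      "The side effects have been about %s.",
      "I'd rate the adverse effects around %s.",
      "Any side effects feel like a %s to me."))
)

# Deterministic template pick keyed by (node_id, seed, subject index).
.pick_template <- function(node_id, slot, seed, subject_index) {
  variants <- .template_bank[[node_id]][[slot]]
  key <- sum(utf8ToInt(paste0(node_id, ":", slot))) +
    as.double(seed) * 131 + as.double(subject_index) * 31
  variants[(key %% length(variants)) + 1]
}

.fmt_severity <- function(value, precision) {
  sprintf(paste0("%.", precision, "f"), value)
}

#' Randomize a cohort 1:1 into active and placebo arms
#'
#' Returns a random permutation of `ceiling(n/2)` ones (active) and
#' `floor(n/2)` zeros (placebo): for odd cohorts the active arm receives the
#' extra subject. Deterministic given the seed.
#'
#' @param n_subjects cohort size (>= 4).
#' @param seed RNG seed.
#' @return integer vector of treatment indicators in `{0, 1}`.
#' @examples
#' table(randomize_cohort(75, seed = 1)) # 37 placebo, 38 active
#' @export
randomize_cohort <- function(n_subjects, seed = 1) {
  if (!is_count(n_subjects, min = 4L))
    pm_config_error("n_subjects must be an integer >= 4 for 1:1 randomization")
  arms <- c(rep(1L, ceiling(n_subjects / 2)), rep(0L, floor(n_subjects / 2)))
  set.seed(derive_seed(seed, 0L))
  sample(arms)
}

#' Simulate ground-truth subject records from the mediation DGP
#'
#' For each subject: treatment `x` from [randomize_cohort()];
#' `z ~ Normal(z_mean, z_sd)`; `m = i_m + a*x + e_m`,
#' `e_m ~ Normal(0, sigma_m)`; `y = i_y + c_prime*x + d*z + b*m + e_y`,
#' `e_y ~ Normal(0, sigma_y)`. Values are never clipped or rounded, so the
#' linear-Gaussian model is exactly well-specified. Each subject draws from
#' its own derived seed stream, so growing the cohort leaves earlier
#' subjects unchanged.
#'
#' @param config a [cohort_config()].
#' @return a data.frame of class `ground_truth` with columns
#'   `subject_id, x, z, m, y`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$params
  n <- config$n_subjects
  x <- randomize_cohort(n, config$seed)
  z <- m <- y <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i))
    z[i] <- rnorm(1, config$z_mean, config$z_sd)
    m[i] <- p$i_m + p$a * x[i] + rnorm(1, 0, p$sigma_m)
    y[i] <- p$i_y + p$c_prime * x[i] + p$d * z[i] + p$b * m[i] + rnorm(1, 0, p$sigma_y)
  }
  structure(data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                       x = x, z = z, m = m, y = y,
                       stringsAsFactors = FALSE),
            class = c("ground_truth", "data.frame"))
}

#' Render one subject record as a patient-chatbot transcript
#'
#' Follows the router: greeting, fatigue yes/no (answered "Yes" iff
#' `y >= fatigue_threshold`), a branch-appropriate stress probe, and a
#' side-effect probe. The fatigue, stress and side-effect severities embed
#' the record's `y`, `z`, `m` rounded to `render_precision` decimals; each
#' severity answer contains exactly one number. Surface wording is chosen
#' deterministically from a fixed template bank.
#'
#' @param record one row of a `ground_truth` data.frame (data.frame or list
#'   with `subject_id, x, z, m, y`).
#' @param config the [cohort_config()] used to simulate the cohort.
#' @param subject_index integer index of the subject within the cohort,
#'   used only to vary template wording (default 1).
#' @return an object of class `transcript`: a list with `subject_id`, `arm`
#'   and `turns` (each turn a list with `role`, `node_id`, `text`).
#' @export
render_transcript <- function(record, config, subject_index = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(c("subject_id", "x", "z", "m", "y") %in% names(record)))
    pm_data_error("record must have fields subject_id, x, z, m, y")
  branch_yes <- record$y >= config$fatigue_threshold
  seed <- config$seed
  pick <- function(node, slot) .pick_template(node, slot, seed, subject_index)
  turn <- function(role, node, text) list(role = role, node_id = node, text = text)
  sev <- function(v) .fmt_severity(v, config$render_precision)

  turns <- list(
    turn("agent", "GREETING", pick("GREETING", "agent")),
    turn("user", "GREETING", pick("GREETING", "user")),
    turn("agent", "FATIGUE_YN", pick("FATIGUE_YN", "agent")),
    turn("user", "FATIGUE_YN",
         pick("FATIGUE_YN", if (branch_yes) "user_yes" else "user_no")),
    turn("agent", "FATIGUE_SEVERITY", pick("FATIGUE_SEVERITY", "agent")),
    turn("user", "FATIGUE_SEVERITY",
         sprintf(pick("FATIGUE_SEVERITY", "user"), sev(record$y))),
    turn("agent", "STRESS",
         pick("STRESS", if (branch_yes) "agent_yes" else "agent_no")),
    turn("user", "STRESS", sprintf(pick("STRESS", "user"), sev(record$z))),
    turn("agent", "SIDE_EFFECTS", pick("SIDE_EFFECTS", "agent")),
    turn("user", "SIDE_EFFECTS",
         sprintf(pick("SIDE_EFFECTS", "user"), sev(record$m)))
  )
  structure(list(subject_id = as.character(record$subject_id),
                 arm = as.integer(record$x), turns = turns),
            class = "transcript")
}

#' Simulate a full cohort: ground truth plus rendered transcripts
#'
#' @param config a [cohort_config()].
#' @return a list with `transcripts` (list of [render_transcript()] outputs)
#'   and `ground_truth` (the [simulate_ground_truth()] data.frame),
#'   index-aligned by `subject_id`.
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_ground_truth(config)
  transcripts <- lapply(seq_len(nrow(truth)), function(i)
    render_transcript(truth[i, ], config, subject_index = i))
  list(transcripts = transcripts, ground_truth = truth)
}

#' Write / read transcripts as JSON Lines
#'
#' One JSON object per subject:
#' `{"subject_id": ..., "arm": 0|1, "turns": [{"role", "node_id", "text"}]}`.
#'
#' @param transcripts list of `transcript` objects.
#' @param path output file path.
#' @return `write_transcripts()` returns `path` invisibly;
#'   `read_transcripts()` returns a list of `transcript` objects.
#' @export
write_transcripts <- function(transcripts, path) {
  lines <- vapply(transcripts, function(tr) {
    jsonlite::toJSON(list(subject_id = tr$subject_id, arm = tr$arm,
                          turns = lapply(tr$turns, function(t)
                            list(role = t$role, node_id = t$node_id, text = t$text))),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) pm_data_error(sprintf("transcript file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    structure(list(subject_id = obj$subject_id, arm = as.integer(obj$arm),
                   turns = obj$turns),
              class = "transcript")
  })
}

#' Write a ground-truth table as CSV
#'
#' @param truth a `ground_truth` data.frame.
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(as.data.frame(truth)[, c("subject_id", "x", "z", "m", "y")],
            path, row.names = FALSE)
  invisible(path)
}
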