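# Parse transcripts back into the analysis table (X, M, Y, Z).
#
# The parser sees only transcript text and trial-side metadata — never the
# ground truth. Treatment x is carried as metadata (the trial system knows
# the assignment; patients do not self-report it). Severities are read from
# the user turn immediately following each severity node; the template
# grammar guarantees exactly one numeric token per answer, and the parser
# enforces that as a checked invariant rather than trusting it.

.number_regex <- "[-+]?[0-9]+(\\.[0-9]+)?"

.extract_numbers <- function(text) {
  m <- gregexpr(.number_regex, text)[[1]]
  if (m[1] == -1L) return(numeric(0))
  as.numeric(regmatches(text, gregexpr(.number_regex, text))[[1]])
}

#' Parse one transcript into an extracted record
#'
#' Pulls the fatigue (`y`), stress (`z`) and side-effect (`m`) severities
#' from the user turns answering the corresponding router nodes, copies the
#' treatment indicator from transcript metadata, and infers the fatigue
#' branch from the yes/no answer.
#'
#' @param transcript a `transcript` object (see [render_transcript()]).
#' @return a one-row data.frame with columns
#'   `subject_id, x, y, z, m, branch`.
#' @export
parse_transcript <- function(transcript) {
  if (is.null(transcript$turns) || length(transcript$turns) == 0L)
    pm_parse_error("transcript has no turns")
  roles <- vapply(transcript$turns, function(t) t$role, character(1))
  nodes <- vapply(transcript$turns, function(t) t$node_id, character(1))
  texts <- vapply(transcript$turns, function(t) t$text, character(1))
  n_turns <- length(roles)
  expected <- rep(c("agent", "user"), length.out = n_turns)
  if (!identical(roles, expected))
    pm_parse_error(sprintf(
      "transcript %s: turns must alternate agent/user starting with agent",
      transcript$subject_id))

  get_answer <- function(node_id) {
    idx <- which(nodes == node_id & roles == "agent")
    if (length(idx) == 0L)
      pm_parse_error(sprintf("transcript %s: incomplete transcript, missing node %s",
                             transcript$subject_id, node_id))
    if (length(idx) > 1L)
      pm_parse_error(sprintf("transcript %s: node %s appears more than once",
                             transcript$subject_id, node_id))
    if (idx + 1L > n_turns || roles[idx + 1L] != "user")
      pm_parse_error(sprintf("transcript %s: node %s has no user answer",
                             transcript$subject_id, node_id))
    texts[idx + 1L]
  }

  severity_of <- function(node_id) {
    ans <- get_answer(node_id)
    nums <- .extract_numbers(ans)
    if (length(nums) == 0L)
      pm_parse_error(sprintf("transcript %s: non-numeric answer at node %s: %s",
                             transcript$subject_id, node_id, ans))
    if (length(nums) > 1L)
      pm_parse_error(sprintf(
        "transcript %s: ambiguous answer at node %s (multiple numbers): %s",
        transcript$subject_id, node_id, ans))
    nums
  }

  yn <- get_answer("FATIGUE_YN")
  branch <- if (grepl("^\\s*yes", yn, ignore.case = TRUE)) "yes"
            else if (grepl("^\\s*no", yn, ignore.case = TRUE)) "no"
            else pm_parse_error(sprintf(
              "transcript %s: cannot infer fatigue branch from answer: %s",
              transcript$subject_id, yn))

  x <- transcript$arm
  if (!is.numeric(x) || !(x %in% c(0, 1)))
    pm_data_error(sprintf("transcript %s: arm metadata must be 0 or 1",
                          transcript$subject_id))

  data.frame(subject_id = as.character(transcript$subject_id),
             x = as.integer(x),
             y = severity_of("FATIGUE_SEVERITY"),
             z = severity_of("STRESS"),
             m = severity_of("SIDE_EFFECTS"),
             branch = branch,
             stringsAsFactors = FALSE)
}

#' Extract a whole cohort of transcripts into an analysis table
#'
#' One row per transcript, input order preserved. Fails fast on the first
#' malformed transcript, naming the offending subject in the error.
#'
#' @param transcripts non-empty list of `transcript` objects.
#' @return a data.frame of class `analysis_table` with columns
#'   `subject_id, x, y, z, m, branch`.
#' @export
extract_cohort <- function(transcripts) {
  if (!is.list(transcripts) || length(transcripts) == 0L)
    pm_data_error("extract_cohort() needs a non-empty list of transcripts")
  rows <- lapply(transcripts, parse_transcript)
  tab <- do.call(rbind, rows)
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup) > 0L)
    pm_data_error(sprintf("duplicate subject_id in cohort: %s",
                          paste(unique(dup), collapse = ", ")))
  structure(tab, class = c("analysis_table", "data.frame"))
}

#' Write / read an analysis table as CSV
#'
#' Header: `subject_id,x,z,m,y,branch`. `read_analysis_table()` validates
#' the schema and accepts tables without the `branch` column (ground-truth
#' CSVs from the fast path).
#'
#' @param table an `analysis_table` data.frame.
#' @param path file path.
#' @export
write_analysis_table <- function(table, path) {
  cols <- c("subject_id", "x", "z", "m", "y",
            if ("branch" %in% names(table)) "branch")
  write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_analysis_table
#' @export
read_analysis_table <- function(path) {
  if (!file.exists(path)) pm_data_error(sprintf("analysis CSV not found: %s", path))
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) pm_parse_error(
                    sprintf("malformed CSV %s: %s", path, conditionMessage(e))))
  required <- c("subject_id", "x", "z", "m", "y")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    pm_data_error(sprintf("analysis CSV %s is missing column(s): %s",
                          path, paste(missing, collapse = ", ")))
  bad <- which(!is.finite(tab$x) | !is.finite(tab$z) |
                 !is.finite(tab$m) | !is.finite(tab$y))
  if (length(bad) > 0L)
    pm_parse_error(sprintf("analysis CSV %s: non-numeric value at data line %d",
                           path, bad[1]))
  structure(tab, class = c("analysis_table", "data.frame"))
}
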