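# Trial-level data container and CSV round-trip.
#
# A session holds one behavioral dataset: one row per trial with the
# participant label, the inspection-target identity (face/noise), the preview
# condition (preview/outline), the derived condition code (FP/FO/NP/NO), the
# choice expressed by the second saccade, and the fixation duration on the
# inspection target in milliseconds.  Durations are stored in ms in files and
# in the session; conversion to seconds happens exactly once, inside the
# model-facing code.

TRIAL_COLUMNS <- c("participant_id", "inspection_identity", "preview",
                   "condition", "choice", "fixation_duration_ms",
                   "inspection_location", "face_side", "trial_index")
REQUIRED_COLUMNS <- TRIAL_COLUMNS[1:6]

condition_code <- function(inspection_identity, preview) {
  paste0(ifelse(inspection_identity == "face", "F", "N"),
         ifelse(preview == "preview", "P", "O"))
}

#' Construct a validated session
#'
#' @param trials Data frame with columns `participant_id`,
#'   `inspection_identity` (`"face"`/`"noise"`), `preview`
#'   (`"preview"`/`"outline"`), `choice` (`"face"`/`"noise"`),
#'   `fixation_duration_ms` (> 0), and optionally `condition`,
#'   `inspection_location` (`"up"`/`"down"`), `face_side`
#'   (`"left"`/`"right"`), `trial_index`.  A stored `condition` column is
#'   checked against the identity x preview combination, never trusted.
#' @param metadata Free-form provenance list (source file, generator seed...).
#' @return An object of class `ddm_session` with elements `trials`,
#'   `participants`, `metadata`.
#' @export
new_session <- function(trials, metadata = list()) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS[REQUIRED_COLUMNS != "condition"],
                          names(trials))
  if (length(missing_cols) > 0)
    stop("session: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  check_levels <- function(col, levels) {
    bad <- which(!(trials[[col]] %in% levels) & !is.na(trials[[col]]))
    if (col %in% REQUIRED_COLUMNS && anyNA(trials[[col]]))
      bad <- sort(c(bad, which(is.na(trials[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("session: unknown %s value '%s' at row %d", col,
                   as.character(trials[[col]][bad[1]]), bad[1]), call. = FALSE)
  }
  check_levels("inspection_identity", c("face", "noise"))
  check_levels("preview", c("preview", "outline"))
  check_levels("choice", c("face", "noise"))

  dur <- trials$fixation_duration_ms
  bad <- which(!is.finite(dur) | dur <= 0)
  if (length(bad) > 0)
    stop(sprintf("session: non-positive or non-finite fixation_duration_ms at row %d",
                 bad[1]), call. = FALSE)

  derived <- condition_code(trials$inspection_identity, trials$preview)
  if ("condition" %in% names(trials)) {
    stored <- as.character(trials$condition)
    nonempty <- !is.na(stored) & stored != ""
    bad <- which(nonempty & stored != derived)
    if (length(bad) > 0)
      stop(sprintf(
        "session: stored condition '%s' contradicts identity/preview ('%s') at row %d",
        stored[bad[1]], derived[bad[1]], bad[1]), call. = FALSE)
  }
  trials$condition <- derived

  for (col in c("inspection_location", "face_side")) {
    if (!col %in% names(trials))
      trials[[col]] <- rep(NA_character_, nrow(trials))
    trials[[col]][trials[[col]] %in% ""] <- NA_character_
  }
  check_levels("inspection_location", c("up", "down"))
  check_levels("face_side", c("left", "right"))
  if (!"trial_index" %in% names(trials))
    trials$trial_index <- rep(NA_integer_, nrow(trials))
  trials$trial_index <- as.integer(trials$trial_index)
  ti_ok <- !is.na(trials$trial_index)
  if (any(ti_ok & trials$trial_index < 1))
    stop("session: trial_index must be >= 1", call. = FALSE)
  if (any(ti_ok)) {
    dup <- duplicated(trials[ti_ok, c("participant_id", "trial_index")])
    if (any(dup))
      stop("session: duplicated trial_index within a participant", call. = FALSE)
  }
  trials$participant_id <- as.character(trials$participant_id)
  trials <- trials[, TRIAL_COLUMNS]
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 participants = unique(trials$participant_id),
                 metadata = metadata),
            class = "ddm_session")
}

#' @export
print.ddm_session <- function(x, ...) {
  cat(sprintf("Dual-saccade session: %d trials, %d participant(s)\n",
              nrow(x$trials), length(x$participants)))
  tab <- table(x$trials$condition)
  cat("  trials per condition:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Table dialect for trial files
#'
#' Describes how an external trial table maps onto the canonical schema:
#' column renames and recodings of the enum levels.  The default dialect is
#' the package's own schema (identity mapping).  This is the adapter point
#' for externally deposited datasets whose column names differ.
#'
#' @param columns Named character vector mapping canonical column names to
#'   the names used in the file, e.g.
#'   `c(participant_id = "subject", choice = "sacc2_target")`.
#' @param levels Named list mapping canonical columns to named character
#'   vectors recoding file values to canonical values, e.g.
#'   `list(choice = c(face = "1", noise = "0"))` (canonical = file value).
#' @param duration_unit `"ms"` or `"s"`; durations are converted to ms on
#'   read.
#' @return A list of class `trial_dialect`.
#' @export
trial_dialect <- function(columns = character(), levels = list(),
                          duration_unit = c("ms", "s")) {
  duration_unit <- match.arg(duration_unit)
  structure(list(columns = columns, levels = levels,
                 duration_unit = duration_unit),
            class = "trial_dialect")
}

#' Read a trial table
#'
#' Reads a CSV of trial-level data (comma-separated, header, UTF-8, `.`
#' decimal), applies the dialect mapping, validates it and returns a session.
#' The condition column is always recomputed from identity x preview and
#' checked against any stored condition column.
#'
#' @param path File path.
#' @param dialect A [trial_dialect()]; defaults to the canonical schema.
#' @return A `ddm_session`.
#' @export
read_trials <- function(path, dialect = trial_dialect()) {
  if (!file.exists(path)) stop("read_trials: file not found: ", path,
                               call. = FALSE)
  raw <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                       progress = FALSE))
  if (length(dialect$columns) > 0) {
    for (canon in names(dialect$columns)) {
      file_col <- dialect$columns[[canon]]
      if (!file_col %in% names(raw))
        stop("read_trials: dialect column not in file: ", file_col,
             call. = FALSE)
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(setdiff(REQUIRED_COLUMNS, "condition"), names(raw))
  if (length(missing_cols) > 0)
    stop("read_trials: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in names(dialect$levels)) {
    map <- dialect$levels[[col]]
    rev_map <- stats::setNames(names(map), as.character(map))
    raw[[col]] <- unname(rev_map[as.character(raw[[col]])])
  }
  if (dialect$duration_unit == "s")
    raw$fixation_duration_ms <- raw$fixation_duration_ms * 1000
  new_session(raw, metadata = list(source = path))
}

#' Write a trial table
#'
#' Emits the canonical CSV schema with a deterministic column order; the file
#' round-trips exactly through [read_trials()] (readr writes shortest
#' round-trip representations of doubles).
#'
#' @param session A `ddm_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(session, path) {
  stopifnot(inherits(session, "ddm_session"))
  readr::write_csv(session$trials[, TRIAL_COLUMNS], path, na = "",
                   progress = FALSE)
  invisible(path)
}

#' Summarize a session for downstream analysis
#'
#' Reports, per participant, the trial counts per condition, the counts in
#' every condition x choice cell, and the fixation-duration range, and flags
#' empty condition x choice cells (which force exclusions in the
#' condition x outcome ANOVA).
#'
#' @param session A `ddm_session`.
#' @return A list of class `session_report` with elements
#'   `condition_counts` (participant x condition), `cell_counts` (long data
#'   frame with condition x choice counts), `duration_range`, `empty_cells`
#'   (data frame of flagged participant/condition/choice cells), `n_trials`.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "ddm_session"))
  tr <- session$trials
  cond_tab <- table(participant = tr$participant_id,
                    condition = factor(tr$condition, levels = CONDITIONS))
  cell <- as.data.frame(table(
    participant = tr$participant_id,
    condition = factor(tr$condition, levels = CONDITIONS),
    choice = factor(tr$choice, levels = c("face", "noise"))),
    stringsAsFactors = FALSE)
  names(cell)[names(cell) == "Freq"] <- "n"
  # only flag empty choice cells inside conditions the participant performed
  performed <- cell$participant != "" &
    cond_tab[cbind(cell$participant, cell$condition)] > 0
  empty <- cell[cell$n == 0 & performed, c("participant", "condition", "choice")]
  rownames(empty) <- NULL
  dur <- range(tr$fixation_duration_ms)
  structure(list(condition_counts = unclass(cond_tab),
                 cell_counts = cell,
                 duration_range = dur,
                 empty_cells = empty,
                 n_trials = nrow(tr)),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("Session report:", x$n_trials, "trials\n")
  print(x$condition_counts)
  cat(sprintf("fixation durations: %.0f-%.0f ms\n",
              x$duration_range[1], x$duration_range[2]))
  if (nrow(x$empty_cells) > 0) {
    cat("empty condition x choice cells:\n")
    print(x$empty_cells)
  } else cat("no empty condition x choice cells\n")
  invisible(x)
}
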