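#' Construct a validated stylus drawing recording
#'
#' A recording is one spiral drawn by one hand in one repetition: an ordered
#' multivariate time series of timestamp, x/y position and pen force sampled
#' at a nominal 240 Hz. Coordinates are centimetres with the origin at the
#' spiral centre (y up); timestamps are seconds from the first sample; force
#' is the dimensionless stylus pressure scale where 1 is an average input.
#'
#' @param participant_id Opaque participant identifier.
#' @param hand `"left"` or `"right"`.
#' @param repetition Repetition index, 1 or 2.
#' @param samples Data frame with numeric columns `t`, `x`, `y`, `force`.
#' @param nominal_rate Nominal sampling rate in Hz (default 240).
#' @return An object of class `drawing_recording`.
#' @export
drawing_recording <- function(participant_id, hand, repetition, samples,
                              nominal_rate = 240) {
  hand <- match.arg(hand, c("left", "right"))
  repetition <- as.integer(repetition)
  if (!repetition %in% c(1L, 2L)) {
    stop("validation error: repetition must be 1 or 2")
  }
  if (!is.data.frame(samples)) {
    stop("validation error: samples must be a data frame")
  }
  missing_cols <- setdiff(c("t", "x", "y", "force"), names(samples))
  if (length(missing_cols) > 0L) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- samples[, c("t", "x", "y", "force")]
  if (nrow(samples) < 2L) {
    stop("validation error: a recording needs at least 2 samples")
  }
  for (col in names(samples)) {
    v <- samples[[col]]
    if (!is.numeric(v)) {
      stop(sprintf("validation error: column '%s' is not numeric", col))
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("validation error: non-finite value in column '%s' at row %d",
                   col, bad[1L]))
    }
  }
  if (any(diff(samples$t) < 0)) {
    stop(sprintf("validation error: timestamps decrease at row %d",
                 which(diff(samples$t) < 0)[1L] + 1L))
  }
  if (any(samples$force < 0)) {
    stop(sprintf("validation error: negative force at row %d",
                 which(samples$force < 0)[1L]))
  }
  structure(
    list(participant_id = as.character(participant_id), hand = hand,
         repetition = repetition, samples = samples,
         nominal_rate = nominal_rate),
    class = "drawing_recording"
  )
}

#' @export
print.drawing_recording <- function(x, ...) {
  cat(sprintf("<drawing_recording> %s %s hand rep %d: %d samples over %.2f s\n",
              x$participant_id, x$hand, x$repetition, nrow(x$samples),
              diff(range(x$samples$t))))
  invisible(x)
}

#' Construct a validated 30-item yes/no questionnaire response
#'
#' The non-motor symptom questionnaire has exactly 30 binary items; the
#' summary score `QYes` (see [qyes()]) counts the yes answers.
#'
#' @param items Vector of 30 answers coded 0/1 (or logical).
#' @return Object of class `questionnaire_response`.
#' @export
questionnaire_response <- function(items) {
  if (is.logical(items)) items <- as.integer(items)
  if (length(items) != 30L) {
    stop(sprintf("validation error: questionnaire must have 30 items, got %d",
                 length(items)))
  }
  if (anyNA(items) || !all(items %in% c(0L, 1L))) {
    bad <- which(is.na(items) | !(items %in% c(0L, 1L)))[1L]
    stop(sprintf("validation error: non-binary questionnaire item at position %d",
                 bad))
  }
  structure(list(items = as.integer(items)), class = "questionnaire_response")
}

#' Construct a participant record
#'
#' Bundles a participant's group label (`CG` control, `PD` Parkinson's
#' Disease, `DD` diverse movement disorders), demographics, optional
#' Hoehn–Yahr stage (PD only), up to four drawing recordings (2 hands x 2
#' repetitions) and the questionnaire response.
#'
#' @param participant_id Identifier, unique within a cohort.
#' @param group `"CG"`, `"PD"` or `"DD"`.
#' @param age Age in years.
#' @param gender `"female"` or `"male"`.
#' @param recordings List of [drawing_recording()] objects.
#' @param questionnaire A [questionnaire_response()].
#' @param hoehn_yahr Optional ordinal stage in \{1, 2, 2.5, 3, 4, 5\};
#'   only meaningful (and only allowed) for the PD group.
#' @return Object of class `participant_record`.
#' @export
participant_record <- function(participant_id, group, age, gender,
                               recordings, questionnaire, hoehn_yahr = NULL) {
  group <- match.arg(group, c("CG", "PD", "DD"))
  gender <- match.arg(gender, c("female", "male"))
  if (!is.null(hoehn_yahr)) {
    if (group != "PD") {
      stop("validation error: hoehn_yahr is only defined for the PD group")
    }
    if (!hoehn_yahr %in% c(1, 2, 2.5, 3, 4, 5)) {
      stop("validation error: hoehn_yahr must be in {1, 2, 2.5, 3, 4, 5}")
    }
  }
  if (!inherits(questionnaire, "questionnaire_response")) {
    stop("validation error: questionnaire must be a questionnaire_response")
  }
  if (length(recordings) < 1L ||
      !all(vapply(recordings, inherits, logical(1), "drawing_recording"))) {
    stop("validation error: recordings must be a non-empty list of drawing_recording")
  }
  keys <- vapply(recordings, function(r) paste(r$hand, r$repetition), "")
  if (anyDuplicated(keys)) {
    stop(sprintf("validation error: duplicate recording slot '%s' for %s",
                 keys[anyDuplicated(keys)], participant_id))
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         age = as.numeric(age), gender = gender, hoehn_yahr = hoehn_yahr,
         recordings = recordings, questionnaire = questionnaire),
    class = "participant_record"
  )
}

#' Construct a cohort dataset
#'
#' @param participants List of [participant_record()] objects with unique ids;
#'   every participant must have at least one recording per hand.
#' @return Object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(participants) {
  if (!all(vapply(participants, inherits, logical(1), "participant_record"))) {
    stop("validation error: participants must be participant_record objects")
  }
  ids <- vapply(participants, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("validation error: duplicated participant_id '%s'",
                 ids[anyDuplicated(ids)][1L]))
  }
  for (p in participants) {
    hands <- vapply(p$recordings, `[[`, "", "hand")
    if (!all(c("left", "right") %in% hands)) {
      stop(sprintf("validation error: participant %s lacks a recording for each hand",
                   p$participant_id))
    }
  }
  names(participants) <- ids
  structure(list(participants = participants), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$participants, `[[`, "", "group")
  tab <- table(factor(groups, levels = c("CG", "PD", "DD")))
  cat(sprintf("<cohort_dataset> %d participants (CG %d, PD %d, DD %d)\n",
              length(x$participants), tab[["CG"]], tab[["PD"]], tab[["DD"]]))
  invisible(x)
}

#' Cohort metadata table
#'
#' One row per participant: id, group, age, gender, Hoehn–Yahr stage (NA
#' outside PD) and the questionnaire yes-count.
#'
#' @param cohort A [cohort_dataset()].
#' @return A tibble.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  rows <- lapply(cohort$participants, function(p) {
    tibble::tibble(
      participant_id = p$participant_id, group = p$group, age = p$age,
      gender = p$gender,
      hoehn_yahr = if (is.null(p$hoehn_yahr)) NA_real_ else p$hoehn_yahr,
      QYes = qyes(p$questionnaire)
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
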