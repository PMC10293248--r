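#' Write a drawing recording to CSV
#'
#' Plain CSV with columns `t,x,y,force` ("." decimal, header row) preceded by
#' `#`-prefixed header lines carrying the recording metadata
#' (participant_id, hand, repetition, nominal_rate), so a recording file is
#' self-describing and round-trips through [read_recording()].
#'
#' @param rec A [drawing_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "drawing_recording"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("I/O error: cannot open '%s' for writing", path))
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# participant_id: %s", rec$participant_id),
    sprintf("# hand: %s", rec$hand),
    sprintf("# repetition: %d", rec$repetition),
    sprintf("# nominal_rate: %s", format(rec$nominal_rate))
  ), con)
  write.csv(format(rec$samples, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drawing recording from CSV
#'
#' Inverse of [write_recording()]: parses the `#` metadata header and the
#' `t,x,y,force` sample table, then validates through [drawing_recording()]
#' so a malformed file can never yield a partially constructed object.
#'
#' @param path Path to a recording CSV.
#' @param participant_id,hand,repetition Overrides for files without a
#'   metadata header (e.g. exported by other tools).
#' @return A [drawing_recording()].
#' @export
read_recording <- function(path, participant_id = NULL, hand = NULL,
                           repetition = NULL) {
  if (!file.exists(path)) stop(sprintf("I/O error: no such file '%s'", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  samples <- read.csv(text = lines[!grepl("^#", lines)],
                      stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("t", "x", "y", "force"), names(samples))
  if (length(missing_cols) > 0L) {
    stop(sprintf("format error: '%s' is missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  drawing_recording(
    participant_id = participant_id %||% meta$participant_id %||% "unknown",
    hand = hand %||% meta$hand %||% stop("format error: hand not specified"),
    repetition = as.integer(repetition %||% meta$repetition %||%
                              stop("format error: repetition not specified")),
    samples = samples,
    nominal_rate = as.numeric(meta$nominal_rate %||% 240)
  )
}

#' Write a cohort to a directory (manifest + per-recording CSVs)
#'
#' Writes one recording CSV per (participant, hand, repetition) and a JSON
#' manifest `cohort.json` holding participant metadata, the 30-item
#' questionnaire rows, and relative recording paths.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort$participants, function(p) {
    recs <- lapply(p$recordings, function(r) {
      fname <- sprintf("%s_%s_rep%d.csv", p$participant_id, r$hand,
                       r$repetition)
      write_recording(r, file.path(dir, fname))
      list(hand = r$hand, repetition = r$repetition, path = fname)
    })
    list(participant_id = p$participant_id, group = p$group, age = p$age,
         gender = p$gender,
         hoehn_yahr = if (is.null(p$hoehn_yahr)) NULL else p$hoehn_yahr,
         questionnaire = p$questionnaire$items, recordings = recs)
  })
  path <- file.path(dir, "cohort.json")
  jsonlite::write_json(unname(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' Reads the JSON manifest written by [write_cohort()], loads and validates
#' every referenced recording, and returns a fully validated
#' [cohort_dataset()]. Duplicate ids and dangling file references are
#' rejected with the offending participant named.
#'
#' @param manifest Path to `cohort.json` (or the cohort directory).
#' @return A [cohort_dataset()].
#' @export
load_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "cohort.json")
  if (!file.exists(manifest)) {
    stop(sprintf("I/O error: no manifest at '%s'", manifest))
  }
  dir <- dirname(manifest)
  entries <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  participants <- lapply(entries, function(e) {
    recs <- lapply(e$recordings, function(r) {
      rpath <- file.path(dir, r$path)
      if (!file.exists(rpath)) {
        stop(sprintf("I/O error: participant %s references missing file '%s'",
                     e$participant_id, r$path))
      }
      read_recording(rpath, participant_id = e$participant_id,
                     hand = r$hand, repetition = r$repetition)
    })
    participant_record(
      participant_id = e$participant_id, group = e$group, age = e$age,
      gender = e$gender, recordings = recs,
      questionnaire = questionnaire_response(unlist(e$questionnaire)),
      hoehn_yahr = if (length(e$hoehn_yahr) == 0) NULL else
        as.numeric(e$hoehn_yahr)
    )
  })
  cohort_dataset(participants)
}

#' Write a per-participant feature table to CSV
#'
#' @param features Feature tibble from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
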