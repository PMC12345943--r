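# Reading, validating and writing the tidy transcription table.

transcription_cols <- c("language", "group", "speaker_id", "stimulus_type",
                        "item_id", "target_text", "source", "transcript")

#' Check 3-listeners-plus-ASR completeness
#'
#' Every (speaker, item) must carry exactly one transcript from each of
#' `listener_1`, `listener_2`, `listener_3` and `asr`. Violations are
#' reported with the offending speaker/item pairs.
#'
#' @param records A transcription tibble.
#' @return Invisibly `TRUE`; aborts with class
#'   `asragree_completeness_error` otherwise.
#' @export
check_completeness <- function(records) {
  if (!"speaker_id" %in% names(records)) records$speaker_id <- "<speaker>"
  counts <- dplyr::count(records, .data$speaker_id, .data$item_id, .data$source)
  dup <- counts[counts$n > 1L, , drop = FALSE]
  if (nrow(dup) > 0L) {
    rlang::abort(
      c("Duplicate (speaker, item, source) rows:",
        utils::head(sprintf("%s / %s / %s", dup$speaker_id, dup$item_id,
                            dup$source), 5L)),
      class = "asragree_duplicate_error"
    )
  }
  cover <- dplyr::summarise(
    dplyr::group_by(records, .data$speaker_id, .data$item_id),
    missing = paste(setdiff(all_sources, .data$source), collapse = ","),
    .groups = "drop"
  )
  bad <- cover[nzchar(cover$missing), , drop = FALSE]
  if (nrow(bad) > 0L) {
    rlang::abort(
      c("Items without full 3-listener + ASR coverage:",
        utils::head(sprintf("speaker %s item %s (missing: %s)",
                            bad$speaker_id, bad$item_id, bad$missing), 5L)),
      class = "asragree_completeness_error"
    )
  }
  invisible(TRUE)
}

#' Read a transcription table from CSV
#'
#' Expects a UTF-8 CSV with columns `language`, `group`, `speaker_id`,
#' `stimulus_type`, `item_id`, `target_text`, `source`, `transcript`
#' (`transcript` may be empty; `target_text` may not). Validates source
#' levels, non-empty targets, duplicates, and the 3-listener + 1-ASR
#' completeness invariant.
#'
#' @param path CSV file path.
#' @param validate Run structural validation (default `TRUE`).
#' @return A tibble of transcription records.
#' @export
read_transcriptions <- function(path, validate = TRUE) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = "UTF-8"),
    progress = FALSE
  )
  missing_cols <- setdiff(transcription_cols, names(records))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      sprintf("Missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "asragree_schema_error"
    )
  }
  records <- records[transcription_cols]
  records$transcript[is.na(records$transcript)] <- ""
  if (validate) validate_transcriptions(records)
  records
}

#' Validate a transcription tibble
#'
#' @inheritParams check_completeness
#' @return Invisibly `TRUE`; aborts with a named error class on violation.
#' @export
validate_transcriptions <- function(records) {
  bad_source <- setdiff(unique(records$source), all_sources)
  if (length(bad_source) > 0L) {
    rlang::abort(
      sprintf("Unknown source level(s): %s", paste(bad_source, collapse = ", ")),
      class = "asragree_schema_error"
    )
  }
  bad_stim <- setdiff(unique(records$stimulus_type), c("word", "sentence"))
  if (length(bad_stim) > 0L) {
    rlang::abort(
      sprintf("Unknown stimulus_type(s): %s", paste(bad_stim, collapse = ", ")),
      class = "asragree_schema_error"
    )
  }
  empty_target <- which(is.na(records$target_text) | !nzchar(records$target_text))
  if (length(empty_target) > 0L) {
    rlang::abort(
      sprintf("Empty target_text at row(s): %s",
              paste(utils::head(empty_target, 5L), collapse = ", ")),
      class = "asragree_schema_error"
    )
  }
  for (stim in unique(records$stimulus_type)) {
    check_completeness(records[records$stimulus_type == stim, , drop = FALSE])
  }
  invisible(TRUE)
}

#' Write a transcription table to CSV
#'
#' UTF-8 CSV round-trips losslessly through [read_transcriptions()].
#'
#' @param records A transcription tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transcriptions <- function(records, path) {
  readr::write_csv(records[transcription_cols], path, progress = FALSE)
  invisible(path)
}
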