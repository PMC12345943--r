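# Per-speaker intelligibility scoring and listener-ASR agreement.
#
# Input is the tidy transcription table: one row per speaker x item x source,
# where source is one of listener_1, listener_2, listener_3, asr. Every item
# must carry exactly three listener transcripts and one ASR transcript.

listener_sources <- c("listener_1", "listener_2", "listener_3")
all_sources <- c(listener_sources, "asr")

#' Score a single-word transcript against its target
#'
#' A single-word production is correct when the normalized transcript is
#' exactly one token and that token matches the target under the
#' phonemic-identity rule ([words_match()]). Empty and multi-token
#' transcripts are incorrect (omission / extraneous material).
#'
#' @param transcript,target Raw texts; `target` must normalize to one token.
#'   Vectorized over both.
#' @param config A [norm_config()].
#' @param lexicon An [equiv_lexicon()].
#' @return Logical vector: `TRUE` for correct.
#' @examples
#' score_word("Dog!", "dog")       # TRUE
#' score_word("", "dog")           # FALSE
#' score_word("the dog", "dog")    # FALSE
#' @export
score_word <- function(transcript, target,
                       config = norm_config("english"),
                       lexicon = equiv_lexicon()) {
  transcript <- as.character(transcript)
  target <- as.character(target)
  transcript[is.na(transcript)] <- ""
  hyp <- normalize_string(transcript, config)
  tgt <- normalize_string(target, config)
  if (any(!nzchar(tgt) | grepl(" ", tgt, fixed = TRUE))) {
    rlang::abort("Every `target` must normalize to exactly one token.",
                 class = "asragree_stimulus_error")
  }
  single <- nzchar(hyp) & !grepl(" ", hyp, fixed = TRUE)
  single & words_match(hyp, tgt, lexicon)
}

#' Majority status across the three listeners
#'
#' @param statuses Logical vector (or matrix with 3 columns, one row per
#'   item): `TRUE` = scored correct. Three binary statuses always have a
#'   majority.
#' @return The status held by at least two of the three listeners.
#' @examples
#' majority_status(c(TRUE, TRUE, FALSE))  # TRUE
#' @export
majority_status <- function(statuses) {
  if (is.matrix(statuses)) {
    if (ncol(statuses) != 3L) {
      rlang::abort("`statuses` must have one column per listener (3).",
                   class = "asragree_completeness_error")
    }
    return(rowSums(statuses) >= 2L)
  }
  if (length(statuses) != 3L) {
    rlang::abort("`statuses` must contain exactly 3 listener statuses.",
                 class = "asragree_completeness_error")
  }
  sum(statuses) >= 2L
}

# Validate and reshape one speaker's word records into a per-item wide table
# with one logical column per source.
.word_status_wide <- function(records, config, lexicon) {
  check_completeness(records)
  records$correct <- score_word(records$transcript, records$target_text,
                                config, lexicon)
  wide <- tidyr::pivot_wider(
    records[, c("item_id", "source", "correct")],
    names_from = "source", values_from = "correct"
  )
  wide[, c("item_id", all_sources)]
}

#' Per-listener word proportions and the mean listener score
#'
#' Each listener's score is the proportion of the speaker's word items scored
#' correct; the speaker's word intelligibility score is the average of the
#' three listener scores.
#'
#' @param records Transcription rows for one speaker's word items (all four
#'   sources present for every item).
#' @param config A [norm_config()].
#' @param lexicon An [equiv_lexicon()].
#' @return A list with `per_listener` (named numeric, length 3), `mean`, and
#'   `n_items`.
#' @export
listener_word_scores <- function(records, config = norm_config("english"),
                                 lexicon = equiv_lexicon()) {
  wide <- .word_status_wide(records, config, lexicon)
  per_listener <- vapply(wide[listener_sources], mean, numeric(1))
  list(per_listener = per_listener, mean = mean(per_listener),
       n_items = nrow(wide))
}

#' Point-by-point listener-ASR agreement for one speaker's words
#'
#' In `"status"` mode (the default) an item counts as agreement when the
#' ASR's correct/incorrect status equals the status assigned by at least two
#' of the three listeners. In `"string"` mode an item counts as agreement
#' when at least two listeners typed the same normalized transcript and the
#' ASR's normalized transcript equals it; with no string majority the item is
#' a disagreement. The result is agreeing items over the number of word items
#' produced by the speaker.
#'
#' @inheritParams listener_word_scores
#' @param mode `"status"` or `"string"`.
#' @return Proportion in `[0, 1]`.
#' @export
word_agreement <- function(records, mode = c("status", "string"),
                           config = norm_config("english"),
                           lexicon = equiv_lexicon()) {
  mode <- match.arg(mode)
  check_completeness(records)
  if (mode == "status") {
    wide <- .word_status_wide(records, config, lexicon)
    maj <- majority_status(as.matrix(wide[listener_sources]))
    return(mean(maj == wide$asr))
  }
  records$norm <- normalize_string(ifelse(is.na(records$transcript), "",
                                          records$transcript), config)
  wide <- tidyr::pivot_wider(
    records[, c("item_id", "source", "norm")],
    names_from = "source", values_from = "norm"
  )
  strs <- as.matrix(wide[listener_sources])
  agree <- vapply(seq_len(nrow(wide)), function(i) {
    tab <- table(strs[i, ])
    if (max(tab) < 2L) return(FALSE)          # no string majority
    wide$asr[i] == names(tab)[which.max(tab)]
  }, logical(1))
  mean(agree)
}

#' Per-speaker word-level results
#'
#' Computes, for every speaker in the table, the mean listener word score, the
#' ASR word score (proportion of items the single ASR transcript got
#' correct), and the listener-ASR agreement proportion.
#'
#' @param records Word-stimulus transcription rows (any number of speakers).
#' @param mode Agreement mode passed to [word_agreement()].
#' @param config A [norm_config()] or `NULL` to pick per-language defaults
#'   from the `language` column.
#' @param lexicon An [equiv_lexicon()].
#' @return A tibble with one row per speaker: `speaker_id`, `language`,
#'   `group`, `listener_score`, `asr_score`, `agreement`, `n_items`.
#' @export
speaker_word_results <- function(records, mode = c("status", "string"),
                                 config = NULL, lexicon = equiv_lexicon()) {
  mode <- match.arg(mode)
  records <- records[records$stimulus_type == "word", , drop = FALSE]
  if (nrow(records) == 0L) {
    rlang::abort("No word-stimulus records.", class = "asragree_completeness_error")
  }
  dplyr::group_by(records, .data$speaker_id, .data$language, .data$group) |>
    dplyr::group_modify(function(df, key) {
      cfg <- config %||% norm_config(as.character(key$language))
      wide <- .word_status_wide(df, cfg, lexicon)
      ls <- vapply(wide[listener_sources], mean, numeric(1))
      tibble::tibble(
        listener_score = mean(ls),
        asr_score = mean(wide$asr),
        agreement = word_agreement(df, mode = mode, config = cfg,
                                   lexicon = lexicon),
        n_items = nrow(wide)
      )
    }) |>
    dplyr::ungroup()
}

#' Per-speaker sentence-level results
#'
#' For each sentence the percent of target words correctly transcribed is
#' computed for each listener and for the ASR ([sentence_percent_correct()]).
#' The speaker's listener sentence score averages the three listeners within
#' each sentence and then across sentences; the ASR score averages the ASR's
#' per-sentence percent correct across sentences. An "ASR success" is a
#' sentence whose ASR percent correct is equal to or greater than the
#' three-listener average for that sentence; `asr_success` is the proportion
#' of the speaker's sentences that are successes.
#'
#' @param records Sentence-stimulus transcription rows (any number of
#'   speakers).
#' @inheritParams speaker_word_results
#' @return A tibble with one row per speaker: `speaker_id`, `language`,
#'   `group`, `listener_score`, `asr_score`, `asr_success`, `n_sentences`.
#' @export
speaker_sentence_results <- function(records, config = NULL,
                                     lexicon = equiv_lexicon()) {
  records <- records[records$stimulus_type == "sentence", , drop = FALSE]
  if (nrow(records) == 0L) {
    rlang::abort("No sentence-stimulus records.",
                 class = "asragree_completeness_error")
  }
  dplyr::group_by(records, .data$speaker_id, .data$language, .data$group) |>
    dplyr::group_modify(function(df, key) {
      cfg <- config %||% norm_config(as.character(key$language))
      check_completeness(df)
      df$pc <- vapply(seq_len(nrow(df)), function(i) {
        sentence_percent_correct(df$transcript[i], df$target_text[i], cfg, lexicon)
      }, numeric(1))
      per_sentence <- tidyr::pivot_wider(
        df[, c("item_id", "source", "pc")],
        names_from = "source", values_from = "pc"
      )
      lmean <- rowMeans(as.matrix(per_sentence[listener_sources]))
      tibble::tibble(
        listener_score = mean(lmean),
        asr_score = mean(per_sentence$asr),
        asr_success = mean(per_sentence$asr >= lmean),
        n_sentences = nrow(per_sentence)
      )
    }) |>
    dplyr::ungroup()
}
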