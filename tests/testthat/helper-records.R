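# Programmatic fixtures: tidy transcription tables built from correctness
# matrices or explicit transcript matrices.

.sources <- c("listener_1", "listener_2", "listener_3", "asr")

# Word records for one speaker from an n_items x 4 logical correctness
# matrix. Wrong answers are unique per (item, source) so they never agree as
# strings unless transcripts are supplied explicitly.
word_fixture <- function(correct, targets = sprintf("w%02d", seq_len(nrow(correct))),
                         transcripts = NULL, speaker = "s1",
                         language = "english", group = "DS") {
  correct <- as.matrix(correct)
  n <- nrow(correct)
  if (is.null(transcripts)) {
    wrong <- outer(seq_len(n), seq_len(4L),
                   function(i, k) sprintf("zz%02d%d", i, k))
    transcripts <- ifelse(correct, matrix(targets, n, 4L), wrong)
  }
  tibble::tibble(
    language = language, group = group, speaker_id = speaker,
    stimulus_type = "word",
    item_id = rep(sprintf("w%02d", seq_len(n)), 4L),
    target_text = rep(targets, 4L),
    source = rep(.sources, each = n),
    transcript = as.vector(transcripts)
  )
}

# Sentence records for one speaker: `targets` character vector of sentences,
# `transcripts` an n_sentences x 4 character matrix.
sentence_fixture <- function(targets, transcripts, speaker = "s1",
                             language = "english", group = "DS") {
  n <- length(targets)
  transcripts <- matrix(transcripts, n, 4L)
  tibble::tibble(
    language = language, group = group, speaker_id = speaker,
    stimulus_type = "sentence",
    item_id = rep(sprintf("s%02d", seq_len(n)), 4L),
    target_text = rep(targets, 4L),
    source = rep(.sources, each = n),
    transcript = as.vector(transcripts)
  )
}

# A small fully-crossed simulation configuration that runs in well under a
# second; shapes give a clear TD > DS separation.
tiny_sim_config <- function(seed = 11L, sentences = c(TRUE, TRUE, FALSE, FALSE)) {
  sim_config(
    cells = tibble::tibble(
      language = c("hebrew", "hebrew", "english", "english"),
      group = c("DS", "TD", "DS", "TD"),
      n_speakers = c(5L, 5L, 4L, 4L),
      shape1 = c(8, 30, 4, 20),
      shape2 = c(3, 1.5, 3, 2),
      asr_offset = c(-0.6, -0.6, 0.2, 0.2),
      sentences = sentences
    ),
    n_word_items = c(hebrew = 12L, english = 15L),
    n_sentences = 3L,
    confusion_size = 60L,
    seed = seed
  )
}

random_tokens <- function(n, vocab = letters[1:5]) {
  if (n == 0L) character(0) else sample(vocab, n, replace = TRUE)
}
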