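# Synthetic study generator.
#
# Emulates the transcription design the scoring pipeline assumes: two
# languages (Hebrew, English) x two speaker groups (DS, TD) with unbalanced
# cell sizes, a fixed word list per language, a short sentence set (Hebrew
# cells only), exactly three naive listeners plus one ASR transcript per
# stimulus, and group-dependent correctness probabilities.
#
# Correctness is modeled on the logit scale. Each speaker carries a latent
# intelligibility probability theta drawn from a per-cell Beta distribution;
# each production (speaker x item) carries a difficulty deviate d shared by
# the three listeners and the ASR, which is the sole listener-ASR coupling
# mechanism. A listener transcribes a word correctly with probability
# plogis(qlogis(slope * theta) - d); the ASR with probability
# plogis(lambda * qlogis(theta) + delta - d). Wrong words are drawn
# uniformly from a held-out confusion vocabulary.

#' Default cell specification for the synthetic study
#'
#' Four cells emulating the unbalanced two-language, two-group design
#' (24 Hebrew DS, 24 Hebrew TD, 8 English DS, 6 English TD). Beta parameters
#' for the latent speaker intelligibility are chosen by moment-matching the
#' per-cell listener word-score means and SDs the design is meant to emulate
#' (DS speakers lower and more variable than TD; English DS lowest). The
#' per-cell ASR offset `delta` makes ASR lag listeners in Hebrew and roughly
#' match them in English. Sentence stimuli are generated for Hebrew cells
#' only.
#'
#' @return A tibble with columns `language`, `group`, `n_speakers`,
#'   `shape1`, `shape2`, `asr_offset`, `sentences`.
#' @export
default_cells <- function() {
  tibble::tibble(
    language = c("hebrew", "hebrew", "english", "english"),
    group = c("DS", "TD", "DS", "TD"),
    n_speakers = c(24L, 24L, 8L, 6L),
    shape1 = c(12.0, 47.0, 1.84, 19.8),
    shape2 = c(3.0, 0.96, 1.44, 1.96),
    asr_offset = c(-0.8, -0.8, 0.25, 0.25),
    sentences = c(TRUE, TRUE, FALSE, FALSE)
  )
}

#' Simulation configuration
#'
#' Full parameterization of the synthetic study generator.
#'
#' @param cells Cell table as in [default_cells()]; `asr_offset` and
#'   `sentences` columns are optional (defaults: global `asr_offset`, no
#'   sentences).
#' @param n_word_items Named count of word items per language (defaults: 46
#'   Hebrew, 78 English).
#' @param n_sentences Sentences per speaker in sentence-bearing cells.
#' @param sentence_lengths Possible sentence lengths in words.
#' @param sentence_length_probs Sampling probabilities for
#'   `sentence_lengths` (defaults give a mean length of 3.6 words).
#' @param listener_slope Scaling from theta to the listener per-word
#'   correctness probability (applied before the logit).
#' @param asr_slope,asr_offset Slope and offset of the ASR correctness logit;
#'   a cell-level `asr_offset` column overrides the global offset.
#' @param item_difficulty_sd SD of the per-production logit difficulty shared
#'   by listeners and ASR; 0 makes listener and ASR errors independent given
#'   theta.
#' @param confusion_size Size of the held-out wrong-word pool per language.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cells = default_cells(),
                       n_word_items = c(hebrew = 46L, english = 78L),
                       n_sentences = 5L,
                       sentence_lengths = c(3L, 4L),
                       sentence_length_probs = c(0.4, 0.6),
                       listener_slope = 1,
                       asr_slope = 1,
                       asr_offset = 0,
                       item_difficulty_sd = 0.8,
                       confusion_size = 400L,
                       seed = 20260930L) {
  cells <- tibble::as_tibble(cells)
  stopifnot(nrow(cells) > 0L,
            all(c("language", "group", "n_speakers", "shape1", "shape2")
                %in% names(cells)))
  if (!"asr_offset" %in% names(cells)) cells$asr_offset <- asr_offset
  if (!"sentences" %in% names(cells)) cells$sentences <- FALSE
  if (any(cells$shape1 <= 0 | cells$shape2 <= 0)) {
    rlang::abort("Beta shape parameters must be positive.",
                 class = "asragree_config_error")
  }
  if (item_difficulty_sd < 0 || listener_slope <= 0 || listener_slope > 1) {
    rlang::abort("Need item_difficulty_sd >= 0 and listener_slope in (0, 1].",
                 class = "asragree_config_error")
  }
  if (length(sentence_lengths) != length(sentence_length_probs) ||
      any(sentence_length_probs < 0) || sum(sentence_length_probs) <= 0) {
    rlang::abort("Sentence length distribution is invalid.",
                 class = "asragree_config_error")
  }
  structure(
    list(
      cells = cells,
      n_word_items = n_word_items,
      n_sentences = as.integer(n_sentences),
      sentence_lengths = as.integer(sentence_lengths),
      sentence_length_probs = sentence_length_probs / sum(sentence_length_probs),
      listener_slope = listener_slope,
      asr_slope = asr_slope,
      asr_offset = asr_offset,
      item_difficulty_sd = item_difficulty_sd,
      confusion_size = as.integer(confusion_size),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", sum(x$cells$n_speakers), "speakers in",
      nrow(x$cells), "cells; seed", x$seed, "\n")
  print(x$cells)
  invisible(x)
}

# Synthetic word forms: pronounceable-ish random strings, unique, already in
# normalized form (Hebrew pool avoids final letters and diacritics).
.make_vocabulary <- function(language, n) {
  alphabet <- if (language == "hebrew") {
    strsplit("אבגדהוזחטיכלמנסעפצקרשת", "")[[1]]
  } else {
    letters
  }
  words <- character(0)
  while (length(words) < n) {
    len <- sample(3:6, n, replace = TRUE)
    cand <- vapply(len, function(l) {
      paste(sample(alphabet, l, replace = TRUE), collapse = "")
    }, character(1))
    words <- unique(c(words, cand))
  }
  words[seq_len(n)]
}

.listener_prob <- function(theta, d, slope) {
  stats::plogis(stats::qlogis(pmin(slope * theta, 1 - 1e-12)) - d)
}

.asr_prob <- function(theta, d, lambda, delta) {
  stats::plogis(lambda * stats::qlogis(theta) + delta - d)
}

#' Simulate a complete synthetic transcription study
#'
#' Generates the full tidy transcription table (3 listeners + 1 ASR per
#' stimulus) together with the generating truth, deterministically under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_study`: a list with `records` (the
#'   tidy transcription tibble), `truth` (a list with per-speaker `speakers`
#'   — cell, theta —, per-production `difficulty`, and the per-record
#'   correctness indicator in `records_truth`), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  languages <- unique(config$cells$language)
  vocab <- lapply(stats::setNames(languages, languages), function(lang) {
    n_items <- config$n_word_items[[lang]]
    pool <- .make_vocabulary(lang, n_items + config$confusion_size)
    list(targets = pool[seq_len(n_items)],
         confusion = pool[n_items + seq_len(config$confusion_size)])
  })

  speakers <- list(); records <- list(); difficulties <- list()
  for (ci in seq_len(nrow(config$cells))) {
    cell <- config$cells[ci, ]
    lang <- cell$language
    theta <- stats::rbeta(cell$n_speakers, cell$shape1, cell$shape2)
    ids <- sprintf("%s_%s_%02d", substr(lang, 1, 2), tolower(cell$group),
                   seq_len(cell$n_speakers))
    speakers[[ci]] <- tibble::tibble(
      speaker_id = ids, language = lang, group = cell$group, theta = theta
    )
    targets <- vocab[[lang]]$targets
    confusion <- vocab[[lang]]$confusion

    for (si in seq_along(ids)) {
      # ---- word stimuli ----
      n_it <- length(targets)
      d <- stats::rnorm(n_it, 0, config$item_difficulty_sd)
      p_l <- .listener_prob(theta[si], d, config$listener_slope)
      p_a <- .asr_prob(theta[si], d, config$asr_slope, cell$asr_offset)
      item_ids <- sprintf("w_%03d", seq_len(n_it))
      src_correct <- cbind(
        matrix(stats::runif(3L * n_it) < p_l, n_it, 3L),
        stats::runif(n_it) < p_a
      )
      wrong <- matrix(
        sample(confusion, 4L * n_it, replace = TRUE), n_it, 4L
      )
      txt <- ifelse(src_correct, matrix(targets, n_it, 4L), wrong)
      records[[length(records) + 1L]] <- tibble::tibble(
        language = lang, group = cell$group, speaker_id = ids[si],
        stimulus_type = "word",
        item_id = rep(item_ids, 4L),
        target_text = rep(targets, 4L),
        source = rep(all_sources, each = n_it),
        transcript = as.vector(txt),
        correct = as.vector(src_correct)
      )
      difficulties[[length(difficulties) + 1L]] <- tibble::tibble(
        speaker_id = ids[si], stimulus_type = "word",
        item_id = item_ids, position = NA_integer_, difficulty = d
      )

      # ---- sentence stimuli ----
      if (isTRUE(cell$sentences) && config$n_sentences > 0L) {
        for (sj in seq_len(config$n_sentences)) {
          len <- sample(config$sentence_lengths, 1L,
                        prob = config$sentence_length_probs)
          sent_words <- sample(targets, len, replace = FALSE)
          d_s <- stats::rnorm(len, 0, config$item_difficulty_sd)
          p_l <- .listener_prob(theta[si], d_s, config$listener_slope)
          p_a <- .asr_prob(theta[si], d_s, config$asr_slope, cell$asr_offset)
          ok <- cbind(
            matrix(stats::runif(3L * len) < p_l, len, 3L),
            stats::runif(len) < p_a
          )
          wrong <- matrix(sample(confusion, 4L * len, replace = TRUE), len, 4L)
          words <- ifelse(ok, matrix(sent_words, len, 4L), wrong)
          sid <- sprintf("s_%02d", sj)
          records[[length(records) + 1L]] <- tibble::tibble(
            language = lang, group = cell$group, speaker_id = ids[si],
            stimulus_type = "sentence",
            item_id = sid,
            target_text = paste(sent_words, collapse = " "),
            source = all_sources,
            transcript = apply(words, 2L, paste, collapse = " "),
            correct = NA
          )
          difficulties[[length(difficulties) + 1L]] <- tibble::tibble(
            speaker_id = ids[si], stimulus_type = "sentence",
            item_id = sid, position = seq_len(len), difficulty = d_s
          )
        }
      }
    }
  }

  records <- dplyr::bind_rows(records)
  structure(
    list(
      records = records[transcription_cols],
      truth = list(
        speakers = dplyr::bind_rows(speakers),
        difficulty = dplyr::bind_rows(difficulties),
        records_truth = records$correct
      ),
      config = config
    ),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study>", nrow(x$truth$speakers), "speakers,",
      nrow(x$records), "transcription records (seed", x$config$seed, ")\n")
  invisible(x)
}

# P(at least 2 of 3 independent listeners correct), per-word probability p.
.p_majority <- function(p) p^3 + 3 * p^2 * (1 - p)

#' Expected per-cell statistics under the generative model
#'
#' Rao-Blackwellized Monte-Carlo expectations of the word-level listener
#' score, ASR score, and status-mode listener-ASR agreement per cell:
#' `n_draws` pairs (theta, d) are drawn from the generative distributions and
#' the conditional expectations (which are available in closed form given
#' theta and d) are averaged. Conditional on theta and d, the three listeners
#' are independent Bernoulli(p_L), so the majority is correct with
#' probability `p_L^3 + 3 p_L^2 (1 - p_L)` and the status agreement is
#' `P(maj correct) p_A + P(maj incorrect) (1 - p_A)`.
#'
#' @param config A [sim_config()].
#' @param n_draws Monte-Carlo draws per cell.
#' @param seed Seed for the expectation computation (independent of
#'   `config$seed`).
#' @return A tibble per cell: `language`, `group`, `listener_score`,
#'   `asr_score`, `agreement`, each with a Monte-Carlo standard error column
#'   (`*_mcse`).
#' @export
expected_statistics <- function(config = sim_config(), n_draws = 200000L,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  purrr::map_dfr(seq_len(nrow(config$cells)), function(ci) {
    cell <- config$cells[ci, ]
    theta <- stats::rbeta(n_draws, cell$shape1, cell$shape2)
    d <- stats::rnorm(n_draws, 0, config$item_difficulty_sd)
    p_l <- .listener_prob(theta, d, config$listener_slope)
    p_a <- .asr_prob(theta, d, config$asr_slope, cell$asr_offset)
    p_maj <- .p_majority(p_l)
    agree <- p_maj * p_a + (1 - p_maj) * (1 - p_a)
    mcse <- function(v) stats::sd(v) / sqrt(n_draws)
    tibble::tibble(
      language = cell$language, group = cell$group,
      listener_score = mean(p_l), listener_score_mcse = mcse(p_l),
      asr_score = mean(p_a), asr_score_mcse = mcse(p_a),
      agreement = mean(agree), agreement_mcse = mcse(agree)
    )
  })
}
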