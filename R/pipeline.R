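# End-to-end pipeline: simulate (or read) -> score -> analyze -> report.

#' Pipeline run configuration
#'
#' @param input Path to a transcription CSV, or `NULL` to simulate a study
#'   with `sim`.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param lexicon_path Optional path to an equivalence lexicon file
#'   ([read_lexicon()]).
#' @param agreement_mode `"status"` or `"string"` (see [word_agreement()]).
#' @param analyses Character subset of `c("correlations", "anova",
#'   "split_plot", "regressions", "normality")`.
#' @param out_dir Output directory for the report files, or `NULL` to skip
#'   writing.
#' @param seed Integer seed for the run; overrides `sim$seed` so one value
#'   controls all randomness.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL,
                       sim = sim_config(),
                       lexicon_path = NULL,
                       agreement_mode = c("status", "string"),
                       analyses = c("correlations", "anova", "split_plot",
                                    "regressions", "normality"),
                       out_dir = NULL,
                       seed = sim$seed) {
  agreement_mode <- match.arg(agreement_mode)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!is.null(input) && !file.exists(input)) {
    rlang::abort(sprintf("Input file not found: %s", input),
                 class = "asragree_config_error")
  }
  sim$seed <- as.integer(seed)
  structure(
    list(input = input, sim = sim, lexicon_path = lexicon_path,
         agreement_mode = agreement_mode, analyses = analyses,
         out_dir = out_dir, seed = as.integer(seed),
         schema_version = asragree_schema_version),
    class = "run_config"
  )
}

# Per-cell descriptive block (mean/SD/range), one row per cell x measure.
.cell_summary <- function(results, measures) {
  tidyr::pivot_longer(results, dplyr::all_of(measures),
                      names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$language, .data$group, .data$measure) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value), sd = stats::sd(.data$value),
      min = min(.data$value), max = max(.data$value),
      .groups = "drop"
    )
}

#' Run the full scoring and analysis pipeline
#'
#' Simulates (or reads) a transcription study, computes per-speaker word and
#' sentence results, runs the configured analyses, and assembles a report
#' bundle. The run is a pure function of (input files, configuration, seed):
#' identical inputs give byte-identical written reports.
#'
#' @param config A [run_config()].
#' @return A report bundle (list) with elements `meta`, `cell_summary`,
#'   `word_results`, `sentence_results` (possibly `NULL`), and `analyses`.
#'   If `config$out_dir` is set the bundle is also written by
#'   [write_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  lexicon <- if (is.null(config$lexicon_path)) equiv_lexicon()
             else read_lexicon(config$lexicon_path)

  if (is.null(config$input)) {
    study <- simulate_study(config$sim)
    records <- study$records
  } else {
    records <- read_transcriptions(config$input)
  }

  word_results <- speaker_word_results(records, mode = config$agreement_mode,
                                       lexicon = lexicon)
  has_sentences <- any(records$stimulus_type == "sentence")
  sentence_results <- if (has_sentences) {
    speaker_sentence_results(records, lexicon = lexicon)
  } else NULL

  analyses <- list()

  if ("correlations" %in% config$analyses) {
    # degenerate cells (e.g. every score identical) report NA, not an error
    safe_cor <- function(d, ...) {
      tryCatch(pearson_cor(d$listener_score, d$asr_score),
               asragree_degenerate_error = function(e)
                 tibble::tibble(r = NA_real_, p = NA_real_, n = nrow(d)))
    }
    word_cor <- word_results |>
      dplyr::group_by(.data$language, .data$group) |>
      dplyr::group_modify(safe_cor) |>
      dplyr::ungroup() |>
      dplyr::mutate(stimulus = "word", .before = 1L)
    sent_cor <- if (!is.null(sentence_results)) {
      sentence_results |>
        dplyr::group_by(.data$language, .data$group) |>
        dplyr::group_modify(safe_cor) |>
        dplyr::ungroup() |>
        dplyr::mutate(stimulus = "sentence", .before = 1L)
    } else NULL
    analyses$correlations <- dplyr::bind_rows(word_cor, sent_cor)
  }

  if ("normality" %in% config$analyses) {
    norm_word <- normality_screen(word_results$agreement)
    norm_sent <- if (!is.null(sentence_results) &&
                     nrow(sentence_results) >= 4L) {
      normality_screen(sentence_results$asr_success)
    } else NULL
    analyses$normality <- dplyr::bind_rows(
      dplyr::mutate(norm_word, stimulus = "word", .before = 1L),
      if (!is.null(norm_sent))
        dplyr::mutate(norm_sent, stimulus = "sentence", .before = 1L)
    )
  }

  if ("anova" %in% config$analyses &&
      length(unique(word_results$language)) >= 2L &&
      length(unique(word_results$group)) >= 2L &&
      all(table(word_results$group, word_results$language) > 0L)) {
    fit <- two_way_anova(word_results$agreement, word_results$group,
                         word_results$language,
                         labels = c("group", "language"))
    analyses$word_anova <- fit$table
    analyses$word_anova_degenerate <- fit$degenerate
    if (!fit$degenerate) analyses$word_contrasts <- emm_pairwise(fit)
  }

  if ("split_plot" %in% config$analyses && !is.null(sentence_results) &&
      length(unique(sentence_results$group)) >= 2L) {
    # Within-subject comparison of the listener-ASR agreement measure across
    # stimulus types: point-by-point agreement for words, ASR-success
    # proportion for sentences. Restricted to languages with sentence data;
    # subjects lacking either stimulus type are dropped (listwise) inside
    # split_plot_anova.
    langs <- unique(sentence_results$language)
    ww <- word_results[word_results$language %in% langs,
                       c("speaker_id", "group", "agreement")]
    names(ww)[3L] <- "value"; ww$stimulus <- "word"
    ss <- sentence_results[, c("speaker_id", "group", "asr_success")]
    ss <- as.data.frame(ss); names(ss)[3L] <- "value"; ss$stimulus <- "sentence"
    long <- dplyr::bind_rows(ww, ss)
    sp <- split_plot_anova(long$value, long$group, long$stimulus,
                           long$speaker_id)
    analyses$split_plot <- sp$table
    analyses$split_plot_n_subjects <- sp$n_subjects
    analyses$split_plot_n_dropped <- sp$n_dropped
    analyses$split_plot_contrasts <- emm_pairwise(sp)
  }

  if ("regressions" %in% config$analyses) {
    # a subgroup with zero predictor variance voids the family, with a note
    safe_reg <- function(x, y, g) {
      tryCatch(subgroup_regressions(x, y, g),
               asragree_degenerate_error = function(e) conditionMessage(e))
    }
    analyses$word_regressions <- safe_reg(
      word_results$listener_score, word_results$agreement,
      paste(word_results$group, word_results$language)
    )
    if (!is.null(sentence_results)) {
      analyses$sentence_regressions <- safe_reg(
        sentence_results$listener_score, sentence_results$asr_success,
        paste(sentence_results$group, sentence_results$language)
      )
    }
  }

  cell_summary <- dplyr::bind_rows(
    dplyr::mutate(
      .cell_summary(word_results,
                    c("listener_score", "asr_score", "agreement")),
      stimulus = "word", .before = 1L),
    if (!is.null(sentence_results))
      dplyr::mutate(
        .cell_summary(sentence_results,
                      c("listener_score", "asr_score", "asr_success")),
        stimulus = "sentence", .before = 1L)
  )

  config_for_hash <- config[c("input", "lexicon_path", "agreement_mode",
                              "analyses", "seed")]
  config_for_hash$sim <- unclass(config$sim)
  bundle <- list(
    meta = list(
      schema_version = config$schema_version,
      config_hash = rlang::hash(config_for_hash),
      seed = config$seed,
      agreement_mode = config$agreement_mode,
      n_speakers = length(unique(records$speaker_id)),
      n_records = nrow(records)
    ),
    cell_summary = cell_summary,
    word_results = word_results,
    sentence_results = sentence_results,
    analyses = analyses
  )
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Writes `report.json` (the full bundle), `word_results.csv`,
#' `sentence_results.csv` (when present), `contrasts.csv` (all EMM contrast
#' rows, word-level and split-plot), and a plain-text `summary.txt` with the
#' per-cell descriptive table and the analysis tables. Every file embeds or
#' accompanies the schema version, configuration hash, and seed recorded in
#' `bundle$meta`; outputs carry no timestamps so identical runs are
#' byte-identical.
#'
#' @param bundle A report bundle from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    bundle, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null", null = "null"
  )
  readr::write_csv(bundle$word_results, file.path(dir, "word_results.csv"),
                   progress = FALSE)
  if (!is.null(bundle$sentence_results)) {
    readr::write_csv(bundle$sentence_results,
                     file.path(dir, "sentence_results.csv"), progress = FALSE)
  }
  contrasts <- dplyr::bind_rows(
    if (!is.null(bundle$analyses$word_contrasts))
      dplyr::mutate(bundle$analyses$word_contrasts, family = "word",
                    .before = 1L),
    if (!is.null(bundle$analyses$split_plot_contrasts))
      dplyr::mutate(bundle$analyses$split_plot_contrasts,
                    family = "word_sentence", .before = 1L)
  )
  if (!is.null(contrasts) && NROW(contrasts) > 0L) {
    names(contrasts) <- c("family", "Contrast", "Estimate", "SE", "df",
                          "t Ratio", "p Value")
    readr::write_csv(contrasts, file.path(dir, "contrasts.csv"),
                     progress = FALSE)
  }

  txt <- c(
    "asragree pipeline report",
    sprintf("schema_version: %s", bundle$meta$schema_version),
    sprintf("config_hash: %s", bundle$meta$config_hash),
    sprintf("seed: %d", bundle$meta$seed),
    sprintf("speakers: %d  records: %d", bundle$meta$n_speakers,
            bundle$meta$n_records),
    "", "== Per-cell summary (mean / SD / range) ==",
    utils::capture.output(print(as.data.frame(bundle$cell_summary),
                                digits = 4))
  )
  for (nm in names(bundle$analyses)) {
    obj <- bundle$analyses[[nm]]
    if (is.data.frame(obj)) {
      txt <- c(txt, "", sprintf("== %s ==", nm),
               utils::capture.output(print(as.data.frame(obj), digits = 4)))
    } else {
      txt <- c(txt, "", sprintf("%s: %s", nm, paste(obj, collapse = " ")))
    }
  }
  writeLines(txt, file.path(dir, "summary.txt"), useBytes = TRUE)
  invisible(dir)
}
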