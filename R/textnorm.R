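# Text normalization for Hebrew and English transcripts.
#
# Listener and ASR transcripts are free-typed UTF-8 text; before any scoring
# they are folded into comparable token sequences. Hebrew typing conventions
# vary in diacritics (niqqud, cantillation) and in the use of final letter
# forms, so both are normalized away by default for Hebrew.

#' Normalization configuration
#'
#' Describes how raw transcripts are folded into comparable token sequences
#' before word-identity decisions. Defaults depend on `language`: Hebrew
#' configurations strip pointing diacritics (niqqud and cantillation) and fold
#' final letter forms; both languages lowercase, strip Unicode punctuation and
#' collapse whitespace.
#'
#' @param language `"hebrew"` or `"english"`.
#' @param lowercase Fold case (only meaningful for scripts with case).
#' @param strip_punctuation Remove all characters in the Unicode punctuation
#'   category (`\\p{P}`), not just an ASCII list, so gershayim and Hebrew
#'   quote marks are covered.
#' @param strip_hebrew_points Remove Unicode combining marks (`\\p{M}`),
#'   which in Hebrew text removes niqqud and cantillation.
#' @param fold_final_letters Map the Hebrew final forms (ך ם ן ף ץ) to their
#'   non-final counterparts (כ מ נ פ צ).
#' @param collapse_whitespace Trim and collapse runs of whitespace to single
#'   separators.
#'
#' @return An object of class `norm_config`.
#' @examples
#' normalize_text("Dog!", norm_config("english"))
#' @export
norm_config <- function(language = c("hebrew", "english"),
                        lowercase = TRUE,
                        strip_punctuation = TRUE,
                        strip_hebrew_points = NULL,
                        fold_final_letters = NULL,
                        collapse_whitespace = TRUE) {
  language <- match.arg(language)
  if (is.null(strip_hebrew_points)) strip_hebrew_points <- language == "hebrew"
  if (is.null(fold_final_letters)) fold_final_letters <- language == "hebrew"
  structure(
    list(
      language = language,
      lowercase = isTRUE(lowercase),
      strip_punctuation = isTRUE(strip_punctuation),
      strip_hebrew_points = isTRUE(strip_hebrew_points),
      fold_final_letters = isTRUE(fold_final_letters),
      collapse_whitespace = isTRUE(collapse_whitespace)
    ),
    class = "norm_config"
  )
}

#' @export
print.norm_config <- function(x, ...) {
  flags <- vapply(x[-1], function(f) if (isTRUE(f)) "on" else "off", character(1))
  cat("<norm_config> language:", x$language, "\n")
  cat(paste0("  ", names(flags), ": ", flags, collapse = "\n"), "\n")
  invisible(x)
}

# Hebrew final forms and their regular counterparts.
.heb_finals <- "ךםןףץ"
.heb_regulars <- "כמנפצ"

#' Normalize a character vector to cleaned strings
#'
#' Vectorized workhorse behind [normalize_text()]: applies the configured
#' folds and returns one whitespace-collapsed string per input element
#' (possibly `""`).
#'
#' @param x Character vector of raw transcripts.
#' @param config A [norm_config()].
#' @return Character vector of the same length.
#' @export
normalize_string <- function(x, config = norm_config("english")) {
  stopifnot(inherits(config, "norm_config"))
  if (!is.character(x)) {
    rlang::abort("`x` must be a character vector.", class = "asragree_type_error")
  }
  x <- enc2utf8(x)
  if (config$strip_hebrew_points) x <- gsub("\\p{M}", "", x, perl = TRUE)
  if (config$fold_final_letters) x <- chartr(.heb_finals, .heb_regulars, x)
  if (config$strip_punctuation) x <- gsub("\\p{P}", "", x, perl = TRUE)
  if (config$lowercase) x <- tolower(x)
  if (config$collapse_whitespace) {
    x <- gsub("\\s+", " ", x, perl = TRUE)
    x <- sub("^ ", "", sub(" $", "", x))
  }
  x
}

#' Normalize raw text into a token sequence
#'
#' @param raw A single raw transcript string (UTF-8).
#' @param config A [norm_config()].
#' @return Character vector of non-empty normalized tokens (length 0 if the
#'   input is empty after normalization). Normalization is idempotent.
#' @examples
#' normalize_text("Dog!", norm_config("english"))        # "dog"
#' normalize_text("שָׁלוֹם",
#'                norm_config("hebrew"))                 # "שלום"
#' @export
normalize_text <- function(raw, config = norm_config("english")) {
  if (length(raw) != 1L) {
    rlang::abort("`raw` must be a single string; use `normalize_string()` for vectors.",
                 class = "asragree_type_error")
  }
  if (is.na(raw)) raw <- ""
  cleaned <- normalize_string(raw, config)
  toks <- strsplit(cleaned, " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Equivalence lexicon of phonemically identical word forms
#'
#' The word-correctness rule scores a transcribed word as correct only when it
#' is phonemically identical to the target. Orthographic normalization alone
#' cannot capture every such identity (spelling variants, plene vs. defective
#' matres lectionis), so additional identities are supplied as an explicit,
#' auditable set of unordered pairs of *normalized* word forms. No
#' grapheme-to-phoneme conversion is attempted. The lexicon defaults to empty.
#'
#' @param pairs A two-column data frame (or matrix) of word forms, or `NULL`
#'   for an empty lexicon.
#' @return An object of class `equiv_lexicon`.
#' @examples
#' lex <- equiv_lexicon(data.frame(a = "color", b = "colour"))
#' words_match("colour", "color", lex)
#' @export
equiv_lexicon <- function(pairs = NULL) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    keys <- character(0)
    pairs_df <- tibble::tibble(form_a = character(0), form_b = character(0))
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (ncol(pairs) < 2L) {
      rlang::abort("`pairs` needs two columns of word forms.",
                   class = "asragree_lexicon_error")
    }
    a <- enc2utf8(as.character(pairs[[1]]))
    b <- enc2utf8(as.character(pairs[[2]]))
    keep <- nzchar(a) & nzchar(b) & a != b
    a <- a[keep]; b <- b[keep]
    keys <- unique(paste(pmin(a, b), pmax(a, b), sep = "\u0001"))
    pairs_df <- tibble::tibble(form_a = a, form_b = b)
  }
  structure(list(keys = keys, pairs = pairs_df), class = "equiv_lexicon")
}

#' @export
print.equiv_lexicon <- function(x, ...) {
  cat("<equiv_lexicon>", length(x$keys), "equivalence pair(s)\n")
  invisible(x)
}

#' Read an equivalence lexicon from a delimited file
#'
#' The file format is two-column UTF-8 delimited text (`form_a`, `form_b`),
#' whitespace- or comma-separated, with `#` comment lines.
#'
#' @param path Path to the lexicon file.
#' @return An [equiv_lexicon()].
#' @export
read_lexicon <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(equiv_lexicon())
  parts <- strsplit(lines, "[,\t ]+")
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) {
    rlang::abort(
      sprintf("Lexicon lines without two forms: %s",
              paste(which(bad), collapse = ", ")),
      class = "asragree_lexicon_error"
    )
  }
  equiv_lexicon(data.frame(
    a = vapply(parts, `[[`, character(1), 1L),
    b = vapply(parts, `[[`, character(1), 2L)
  ))
}

#' Decide word identity under the phonemic-identity rule
#'
#' Two normalized tokens match when they are string-identical or declared
#' equivalent in the lexicon. Any partial mismatch — omission or substitution
#' of any part of the word, including morphological elements (e.g. a plural
#' suffix) — is a non-match.
#'
#' @param hypothesis,target Normalized tokens. Vectorized; recycled to common
#'   length.
#' @param lexicon An [equiv_lexicon()].
#' @return Logical vector. Symmetric in its two arguments.
#' @examples
#' words_match("tov", "tov")                                   # TRUE
#' words_match("ילד", "ילדים")  # FALSE
#' @export
words_match <- function(hypothesis, target, lexicon = equiv_lexicon()) {
  stopifnot(inherits(lexicon, "equiv_lexicon"))
  hypothesis <- as.character(hypothesis)
  target <- as.character(target)
  n <- max(length(hypothesis), length(target))
  hypothesis <- rep_len(hypothesis, n)
  target <- rep_len(target, n)
  out <- hypothesis == target
  if (length(lexicon$keys) && any(!out)) {
    idx <- which(!out)
    key <- paste(pmin(hypothesis[idx], target[idx]),
                 pmax(hypothesis[idx], target[idx]), sep = "\u0001")
    out[idx] <- key %in% lexicon$keys
  }
  out & !is.na(out)
}
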