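# Word-level minimum edit-distance alignment.
#
# Sentence scoring needs the number of reference words correctly transcribed,
# which requires a monotone alignment between the hypothesis and the target
# token sequence. Unit costs; a hit (cost 0) requires words_match(), so the
# equivalence lexicon participates in the alignment itself.

#' Align two token sequences by minimum edit distance
#'
#' Computes the classical monotone alignment between a hypothesis and a
#' reference token sequence with unit insertion/deletion/substitution costs.
#' A matched pair (hit) costs 0 and requires [words_match()] under the given
#' lexicon. Among minimum-cost alignments, ties are broken by preferring hits,
#' then substitutions, then deletions.
#'
#' @param hypothesis,reference Character vectors of normalized tokens (may be
#'   empty).
#' @param lexicon An [equiv_lexicon()].
#' @return A list of class `token_alignment` with integer counts `hits`,
#'   `substitutions`, `deletions`, `insertions` and the total edit `cost`.
#'   Always `hits + substitutions + deletions == length(reference)` and
#'   `hits + substitutions + insertions == length(hypothesis)`.
#' @examples
#' align_tokens(c("the", "dog"), c("the", "big", "dog"))
#' @export
align_tokens <- function(hypothesis, reference, lexicon = equiv_lexicon()) {
  hyp <- as.character(hypothesis)
  ref <- as.character(reference)
  nh <- length(hyp)
  nr <- length(ref)

  # DP over (hypothesis prefix, reference prefix). The additive key encodes
  # the lexicographic objective (minimize cost, then maximize hits, then
  # substitutions, then deletions); sequence lengths are far below the 100
  # needed to make the magnitude bands interact. Back-pointers: 1 hit,
  # 2 substitution, 3 deletion, 4 insertion.
  key_hit <- -1e4; key_sub <- 1e8 - 1e2; key_del <- 1e8 - 1; key_ins <- 1e8
  key <- matrix(0, nh + 1L, nr + 1L)
  move <- matrix(0L, nh + 1L, nr + 1L)
  if (nh > 0L) { key[-1L, 1L] <- key_ins * seq_len(nh); move[-1L, 1L] <- 4L }
  if (nr > 0L) { key[1L, -1L] <- key_del * seq_len(nr); move[1L, -1L] <- 3L }
  if (nh > 0L && nr > 0L) {
    match_mat <- matrix(
      words_match(rep(hyp, times = nr), rep(ref, each = nh), lexicon),
      nh, nr
    )
    for (i in seq_len(nh)) {
      for (j in seq_len(nr)) {
        diag_key <- key[i, j] + if (match_mat[i, j]) key_hit else key_sub
        del_key <- key[i + 1L, j] + key_del   # reference token unaccounted for
        ins_key <- key[i, j + 1L] + key_ins   # extra hypothesis token
        best <- min(diag_key, del_key, ins_key)
        key[i + 1L, j + 1L] <- best
        move[i + 1L, j + 1L] <-
          if (diag_key == best) (if (match_mat[i, j]) 1L else 2L)
          else if (del_key == best) 3L
          else 4L
      }
    }
  }

  counts <- c(hit = 0L, sub = 0L, del = 0L, ins = 0L)
  i <- nh + 1L; j <- nr + 1L
  while (i > 1L || j > 1L) {
    m <- move[i, j]
    if (m == 1L) { counts["hit"] <- counts["hit"] + 1L; i <- i - 1L; j <- j - 1L }
    else if (m == 2L) { counts["sub"] <- counts["sub"] + 1L; i <- i - 1L; j <- j - 1L }
    else if (m == 3L) { counts["del"] <- counts["del"] + 1L; j <- j - 1L }
    else { counts["ins"] <- counts["ins"] + 1L; i <- i - 1L }
  }

  structure(
    list(
      hits = unname(counts["hit"]),
      substitutions = unname(counts["sub"]),
      deletions = unname(counts["del"]),
      insertions = unname(counts["ins"]),
      cost = unname(counts["sub"] + counts["del"] + counts["ins"])
    ),
    class = "token_alignment"
  )
}

#' @export
print.token_alignment <- function(x, ...) {
  cat(sprintf("<token_alignment> hits %d, sub %d, del %d, ins %d (cost %d)\n",
              x$hits, x$substitutions, x$deletions, x$insertions, x$cost))
  invisible(x)
}

#' Proportion of target words correctly transcribed in a sentence
#'
#' Normalizes both texts, aligns them, and returns hits divided by the number
#' of reference (target) tokens. Insertions cannot push the score below 0 and
#' the denominator is the target length, so the score stays in `[0, 1]`.
#'
#' @param transcript Raw transcript text.
#' @param target Raw target sentence text; must contain at least one token
#'   after normalization.
#' @param config A [norm_config()].
#' @param lexicon An [equiv_lexicon()].
#' @return Proportion in `[0, 1]`.
#' @examples
#' sentence_percent_correct("the dog", "the big dog")  # 2/3
#' @export
sentence_percent_correct <- function(transcript, target,
                                     config = norm_config("english"),
                                     lexicon = equiv_lexicon()) {
  ref <- normalize_text(target, config)
  if (length(ref) == 0L) {
    rlang::abort("Target sentence is empty after normalization.",
                 class = "asragree_stimulus_error")
  }
  hyp <- normalize_text(transcript, config)
  align_tokens(hyp, ref, lexicon)$hits / length(ref)
}
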