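test_that("single-word scoring follows the phonemic-identity rule", {
  expect_true(score_word("dog", "dog"))
  expect_true(score_word("Dog!", "dog"))
  expect_false(score_word("", "dog"))          # omission
  expect_false(score_word("the dog", "dog"))   # multi-token transcript
  expect_false(score_word("dogs", "dog"))      # morphological addition
  expect_equal(score_word(c("dog", "", "cat"), "dog"),
               c(TRUE, FALSE, FALSE))
  expect_error(score_word("x", "two words"),
               class = "asragree_stimulus_error")
})

test_that("majority status matches exhaustive enumeration of all triples", {
  triples <- expand.grid(l1 = c(TRUE, FALSE), l2 = c(TRUE, FALSE),
                         l3 = c(TRUE, FALSE))
  for (r in seq_len(nrow(triples))) {
    st <- unlist(triples[r, ])
    expect_identical(majority_status(st), sum(st) >= 2)
  }
  expect_identical(majority_status(as.matrix(triples)),
                   rowSums(as.matrix(triples)) >= 2)
  expect_error(majority_status(c(TRUE, FALSE)),
               class = "asragree_completeness_error")
})

test_that("listener word scores average the three listener proportions", {
  # 4-item toy with a known correctness matrix
  correct <- rbind(
    c(TRUE, TRUE, TRUE, TRUE),
    c(TRUE, FALSE, TRUE, FALSE),
    c(FALSE, FALSE, TRUE, TRUE),
    c(TRUE, TRUE, FALSE, FALSE)
  )
  res <- listener_word_scores(word_fixture(correct))
  expect_equal(unname(res$per_listener), c(3 / 4, 2 / 4, 3 / 4))
  expect_equal(res$mean, mean(c(3, 2, 3) / 4))
  expect_equal(res$n_items, 4L)
})

test_that("incomplete listener coverage raises a completeness error", {
  recs <- word_fixture(matrix(TRUE, 3, 4))
  broken <- recs[!(recs$source == "listener_3" & recs$item_id == "w02"), ]
  err <- expect_error(listener_word_scores(broken),
                      class = "asragree_completeness_error")
  expect_match(conditionMessage(err), "w02")
  dup <- rbind(recs, recs[1, ])
  expect_error(listener_word_scores(dup), class = "asragree_duplicate_error")
})

test_that("status-mode agreement equals per-item enumeration", {
  # (majority, ASR) = (C,C), (C,I), (I,I), (I,C) -> agreement 0.5
  correct <- rbind(
    c(TRUE, TRUE, FALSE, TRUE),
    c(TRUE, TRUE, TRUE, FALSE),
    c(FALSE, FALSE, TRUE, FALSE),
    c(FALSE, TRUE, FALSE, TRUE)
  )
  expect_equal(word_agreement(word_fixture(correct)), 0.5)
  expect_equal(word_agreement(word_fixture(matrix(TRUE, 5, 4))), 1)

  set.seed(407)
  for (rep in 1:10) {
    correct <- matrix(runif(50 * 4) < 0.6, 50, 4)
    recs <- word_fixture(correct)
    # enumeration oracle: item-by-item majority vs ASR status
    want <- mean((rowSums(correct[, 1:3]) >= 2) == correct[, 4])
    expect_equal(word_agreement(recs), want)
  }
})

test_that("string-mode agreement needs a string majority matching the ASR", {
  targets <- c("dog", "cat", "sun", "map")
  # item 1: all sources typed the target -> agree
  # item 2: two listeners typed "kat", ASR typed "kat" -> agree (wrong word)
  # item 3: listeners split three ways -> no majority -> disagree
  # item 4: majority "map", ASR "nap" -> disagree
  tr <- rbind(
    c("dog", "dog", "dog", "dog"),
    c("kat", "kat", "cat", "kat"),
    c("sun", "son", "san", "sun"),
    c("map", "map", "mop", "nap")
  )
  recs <- word_fixture(matrix(TRUE, 4, 4), targets = targets, transcripts = tr)
  expect_equal(word_agreement(recs, mode = "string"), 0.5)
})

test_that("status and string agreement coincide when ASR echoes the majority", {
  set.seed(408)
  targets <- sprintf("t%02d", 1:12)
  correct <- matrix(runif(12 * 3) < 0.7, 12, 3)
  # listeners type target when correct, item-specific wrong word otherwise;
  # ASR copies listener majority string exactly
  listener_tr <- ifelse(correct, matrix(targets, 12, 3),
                        matrix(sprintf("w%02d", 1:12), 12, 3))
  maj_str <- vapply(seq_len(12), function(i) {
    tab <- table(listener_tr[i, ])
    names(tab)[which.max(tab)]
  }, character(1))
  tr <- cbind(listener_tr, maj_str)
  recs <- word_fixture(matrix(TRUE, 12, 4), targets = targets, transcripts = tr)
  expect_equal(word_agreement(recs, mode = "status"),
               word_agreement(recs, mode = "string"))
  expect_equal(word_agreement(recs, mode = "string"), 1)
})

test_that("sentence results average listeners within then across sentences", {
  # sentence 1: listeners (1, 2/3, 1/3), ASR 2/3; sentence 2: all perfect
  targets <- c("the big dog", "a red sun")
  tr <- rbind(
    c("the big dog", "the dog", "dog", "the big"),
    c("a red sun", "a red sun", "a red sun", "a red sun")
  )
  res <- speaker_sentence_results(sentence_fixture(targets, tr))
  l1 <- mean(c(1, 2 / 3, 1 / 3))
  expect_equal(res$listener_score, mean(c(l1, 1)))
  expect_equal(res$asr_score, mean(c(2 / 3, 1)))
  # sentence 1: ASR 2/3 >= listener mean 2/3 -> success; sentence 2: success
  expect_equal(res$asr_success, 1)
  expect_equal(res$n_sentences, 2L)
})

test_that("ASR success counts sentences at or above the listener average", {
  # ASR exactly equal to the three-listener average counts as a success
  targets <- c("a b c d e")
  tr <- matrix(c("a b c d", "a b c d", "a b c d", "a b c d"), 1, 4)
  res <- speaker_sentence_results(sentence_fixture(targets, tr))
  expect_equal(res$asr_success, 1)
  # two sentences, ASR (1, 0) vs listener averages (0.5, 0.5) -> 0.5
  targets <- c("a b", "c d")
  tr <- rbind(
    c("a b", "x y", "a y", "a b"),   # listeners 1, 0, 1/2 -> mean 1/2; ASR 1
    c("c d", "x y", "c y", "x y")    # listeners 1, 0, 1/2 -> mean 1/2; ASR 0
  )
  res <- speaker_sentence_results(sentence_fixture(targets, tr))
  expect_equal(res$asr_success, 0.5)
})

test_that("a perfect study yields exactly 1.0 everywhere", {
  cfg <- tiny_sim_config(seed = 21L)
  cfg$cells$shape1 <- 1e6   # theta ~ 1
  cfg$cells$shape2 <- 1e-3
  cfg$item_difficulty_sd <- 0
  cfg$cells$asr_offset <- 50
  study <- simulate_study(cfg)
  wr <- speaker_word_results(study$records)
  expect_true(all(wr$listener_score == 1))
  expect_true(all(wr$asr_score == 1))
  expect_true(all(wr$agreement == 1))
  sr <- speaker_sentence_results(study$records)
  expect_true(all(sr$listener_score == 1))
  expect_true(all(sr$asr_success == 1))
})

test_that("changing one record moves agreement by at most 1/n", {
  set.seed(409)
  correct <- matrix(runif(20 * 4) < 0.6, 20, 4)
  recs <- word_fixture(correct)
  base <- word_agreement(recs)
  for (k in sample(nrow(recs), 8)) {
    mod <- recs
    mod$transcript[k] <- if (mod$transcript[k] == mod$target_text[k])
      "zzznew" else mod$target_text[k]
    expect_lte(abs(word_agreement(mod) - base), 1 / 20 + 1e-12)
  }
})
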