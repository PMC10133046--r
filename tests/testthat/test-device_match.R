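test_that("edit distance matches the recursive oracle and is a metric", {
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(levenshtein("abc", "abc"), 0L)
  expect_identical(levenshtein("", "abc"), 3L)
  set.seed(41)
  rand_str <- function() paste(sample(letters[1:3], sample(0:6, 1),
                                      replace = TRUE), collapse = "")
  for (i in 1:40) {
    a <- rand_str(); b <- rand_str(); c <- rand_str()
    expect_identical(levenshtein(a, b), oracle_levenshtein(a, b))
    expect_identical(levenshtein(a, b), levenshtein(b, a))
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("the 0..100 ratio follows the substitution-cost-2 normalization", {
  expect_identical(ratio_score("abc", "abc"), 100L)
  expect_identical(ratio_score("ab", "cd"), 0L)
  expect_identical(ratio_score("ab", "ac"), 50L)
  expect_identical(ratio_score("", ""), 100L)
  expect_identical(ratio_score("", "abc"), 0L)
})

test_that("token-set ratio is order/duplication invariant and 100 on subsets", {
  expect_identical(token_set_ratio("alpha beta", "beta alpha"), 100L)
  expect_identical(token_set_ratio("alpha beta", "alpha beta alpha"), 100L)
  expect_identical(token_set_ratio("probe x200", "probe x200 kit"), 100L)
  # token-disjoint single words reduce to the plain ratio of sorted words
  expect_identical(token_set_ratio("probe", "valve"),
                   max(ratio_score("", "probe"), ratio_score("", "valve"),
                       ratio_score("probe", "valve")))
  set.seed(42)
  words <- c("cardio", "probe", "pump", "valve", "x1", "kit", "set")
  for (i in 1:30) {
    a <- paste(sample(words, sample(1:5, 1), replace = TRUE),
               collapse = " ")
    b <- paste(sample(words, sample(1:5, 1), replace = TRUE),
               collapse = " ")
    expect_identical(token_set_ratio(a, b), token_set_ratio(b, a))
    shuffled <- paste(sample(strsplit(a, " ")[[1]]), collapse = " ")
    expect_identical(token_set_ratio(a, b), token_set_ratio(shuffled, b))
    ta <- strsplit(a, " ")[[1]]; tb <- strsplit(b, " ")[[1]]
    if (all(ta %in% tb) || all(tb %in% ta))
      expect_identical(token_set_ratio(a, b), 100L)
  }
})

test_that("pair scoring takes the better field pair; empty fields score 0", {
  s <- score_pair("", "", "", "")
  expect_identical(s$score, 0L)
  s <- score_pair("cardio probe x1", "anything else",
                  "cardio probe x1", "zz99")
  expect_identical(s$score, 100L)
  expect_identical(s$field_pair, "device_vs_commercial")
  s <- score_pair("unrelated words", "probe kit ct100",
                  "completely different", "ct100")
  expect_identical(s$field_pair, "commercial_vs_catalogue")
  expect_identical(s$score,
                   token_set_ratio("probe kit ct100", "ct100"))
  # oracle: always the max of the two independently computed pair scores
  set.seed(43)
  words <- c("cardio", "probe", "pump", "x1", "ct100", "kit")
  for (i in 1:20) {
    f <- function() paste(sample(words, sample(1:3, 1)), collapse = " ")
    nd <- f(); nc <- f(); dc <- f(); cat_ <- f()
    expect_identical(score_pair(nd, nc, dc, cat_)$score,
                     max(token_set_ratio(nd, dc),
                         token_set_ratio(nc, cat_)))
  }
})

test_that("threshold schedule walks 95 down to 60 and floors", {
  cands <- data.frame(progressive_id = c("10", "2"),
                      commercial_norm = c("cardio probe x1",
                                          "cardio probe x1"),
                      catalogue_norm = c("", ""),
                      stringsAsFactors = FALSE)
  notice <- list(device_norm = "cardio probe x1", commercial_norm = "")
  hit <- find_best_device(notice, cands)
  expect_identical(hit$accepted_threshold, 95L)
  expect_identical(hit$score, 100L)
  expect_identical(hit$device_id, "2")    # numeric tie-break: 2 < 10
  # single candidate at intermediate score accepts at the right rung
  one <- data.frame(progressive_id = "7",
                    commercial_norm = "cardio pomp y2 extra tokens here",
                    catalogue_norm = "", stringsAsFactors = FALSE)
  hit2 <- find_best_device(notice, one)
  if (!is.null(hit2)) {
    expect_gte(hit2$score, hit2$accepted_threshold)
    expect_identical(hit2$accepted_threshold,
                     as.integer(max(seq(95, 60, -5)[
                       seq(95, 60, -5) <= hit2$score])))
  }
  # nothing at or above the floor
  junk <- data.frame(progressive_id = "1", commercial_norm = "zzzz qqqq",
                     catalogue_norm = "", stringsAsFactors = FALSE)
  expect_null(find_best_device(notice, junk))
  expect_null(find_best_device(notice, junk[0, ]))
})

test_that("iterative schedule is extensionally max-then-floor", {
  set.seed(44)
  words <- c("cardio", "probe", "pump", "valve", "stent", "x1", "z9",
             "kit", "set", "ct100", "bx55")
  for (i in 1:60) {
    n_cand <- sample(1:6, 1)
    cands <- data.frame(
      progressive_id = as.character(sample(1:5000, n_cand)),
      commercial_norm = replicate(n_cand,
        paste(sample(words, sample(1:4, 1)), collapse = " ")),
      catalogue_norm = replicate(n_cand,
        paste(sample(words, sample(0:2, 1)), collapse = " ")),
      stringsAsFactors = FALSE)
    notice <- list(
      device_norm = paste(sample(words, sample(1:4, 1)), collapse = " "),
      commercial_norm = paste(sample(words, sample(0:3, 1)),
                              collapse = " "))
    got <- find_best_device(notice, cands)
    want <- oracle_best_device(notice, cands)
    if (is.null(want)) expect_null(got) else {
      expect_identical(got$device_id, want$device_id)
      expect_identical(got$score, want$score)
      expect_identical(got$accepted_threshold, want$accepted_threshold)
    }
  }
})
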