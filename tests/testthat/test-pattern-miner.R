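# Context-pattern mining: substitution, enumeration, scoring, filtering.

worked_sentence <- paste0(
  '遂于<TIMEX3 tid="t9" Type="DATE" Value="2014-09-22" anchorTimeID="t3">',
  "22/9</TIMEX3>行右乳癌改良根治术")

test_that("substitute_tags replaces each annotation with one placeholder", {
  expect_identical(substitute_tags(worked_sentence),
                   "遂于<TIMEX3>行右乳癌改良根治术")
  expect_identical(substitute_tags('<TIMEX3 tid="t1" Type="DATE" Value="2014">x</TIMEX3>'),
                   "<TIMEX3>")
  two <- paste0('自<TIMEX3 tid="t1" Type="DATE" Value="2014">a</TIMEX3>至',
                '<TIMEX3 tid="t2" Type="DATE" Value="2015">b</TIMEX3>间')
  expect_identical(substitute_tags(two), "自<TIMEX3>至<TIMEX3>间")
  expect_error(substitute_tags("无标注句子"), "no TIMEX3 annotation")
})

test_that("candidate enumeration matches the documented counts", {
  expect_length(enumerate_candidates(substitute_tags(worked_sentence)), 15L)
  expect_identical(enumerate_candidates("<TIMEX3>"), "<TIMEX3>")
  expect_setequal(enumerate_candidates("于<TIMEX3>行"),
                  c("<TIMEX3>", "于<TIMEX3>", "<TIMEX3>行", "于<TIMEX3>行"))
})

test_that("enumeration agrees with the brute-force substring oracle", {
  set.seed(11)
  for (i in 1:60) {
    tpl <- random_templated(sample(0:25, 1), n_ph = sample(1:2, 1))
    max_len <- sample(2:8, 1)
    expect_setequal(enumerate_candidates(tpl, miner_config(max_pattern_len = max_len)),
                    oracle_enumerate(tpl, max_len))
  }
})

test_that("scoring matches exhaustive hand-counted sites on the fixture corpus", {
  fx <- miner_fixture()
  scored <- score_patterns(
    c("<TIMEX3>", "术后<TIMEX3>", "<TIMEX3>余", "术后<TIMEX3>余", "戊<TIMEX3>"),
    fx, "NORM_ANCHOR_EQUALS")
  got <- scored[order(scored$template), ]
  # sites: 5 gold mentions; only fixA t2 has Value equal to its anchor's Value
  expect_identical(got$support[got$template == "<TIMEX3>"], 5L)
  expect_equal(got$confidence[got$template == "<TIMEX3>"], 1 / 5)
  expect_identical(got$support[got$template == "术后<TIMEX3>"], 3L)
  expect_equal(got$confidence[got$template == "术后<TIMEX3>"], 1 / 3)
  expect_identical(got$support[got$template == "<TIMEX3>余"], 2L)
  expect_equal(got$confidence[got$template == "<TIMEX3>余"], 1 / 2)
  expect_identical(got$support[got$template == "术后<TIMEX3>余"], 2L)
  expect_equal(got$confidence[got$template == "术后<TIMEX3>余"], 1 / 2)
  # zero-support candidates carry no confidence and are dropped downstream
  expect_identical(got$support[got$template == "戊<TIMEX3>"], 0L)
  expect_true(is.na(got$confidence[got$template == "戊<TIMEX3>"]))
  expect_false("戊<TIMEX3>" %in% filter_patterns(scored, miner_config(threshold = 0))$template)
})

test_that("threshold keeps confidence exactly 0.8 and drops 0.79", {
  pats <- data.frame(
    template = c("甲<TIMEX3>", "乙<TIMEX3>"), purpose = "NORM_ANCHOR_EQUALS",
    support = c(5L, 100L), confidence = c(0.8, 0.79), stringsAsFactors = FALSE)
  kept <- filter_patterns(pats, miner_config(threshold = 0.8))
  expect_identical(kept$template, "甲<TIMEX3>")
})

test_that("substring reduction keeps the more general template", {
  pats <- data.frame(
    template = c("予<TIMEX3>", "可予<TIMEX3>", "<TIMEX3>办"),
    purpose = "NORM_ANCHOR_EQUALS", support = c(5L, 4L, 5L),
    confidence = c(1.0, 0.9, 1.0), stringsAsFactors = FALSE)
  kept <- filter_patterns(pats, miner_config(threshold = 0.8))
  expect_setequal(kept$template, c("予<TIMEX3>", "<TIMEX3>办"))
  # but a strictly more confident superstring survives
  pats2 <- data.frame(
    template = c("予<TIMEX3>", "可予<TIMEX3>"), purpose = "NORM_ANCHOR_EQUALS",
    support = c(5L, 4L), confidence = c(0.85, 0.95), stringsAsFactors = FALSE)
  expect_setequal(filter_patterns(pats2, miner_config())$template,
                  c("予<TIMEX3>", "可予<TIMEX3>"))
})

test_that("filtered output is substring-minimal and confidences are in [0,1]", {
  pats <- fixture_patterns()
  expect_true(all(pats$confidence >= 0 & pats$confidence <= 1))
  expect_true(all(pats$confidence >= 0.8))
  for (i in seq_len(nrow(pats))) {
    for (j in seq_len(nrow(pats))) {
      if (i == j) next
      sub_ij <- nchar(pats$template[j]) < nchar(pats$template[i]) &&
        grepl(pats$template[j], pats$template[i], fixed = TRUE)
      expect_false(sub_ij && pats$confidence[j] >= pats$confidence[i])
    }
  }
})

test_that("support is additive over corpus concatenation", {
  a <- fixture_corpus(6, 51)
  b <- fixture_corpus(6, 52)
  cand <- c("术后<TIMEX3>余", "<TIMEX3>")
  sa <- score_patterns(cand, a, "NORM_ANCHOR_EQUALS")
  sb <- score_patterns(cand, b, "NORM_ANCHOR_EQUALS")
  sab <- score_patterns(cand, c(a, b), "NORM_ANCHOR_EQUALS")
  expect_identical(sab$support, sa$support + sb$support)
})

test_that("the planted anchor-equality context is recovered at confidence 1", {
  hits <- vapply(1:5, function(s) {
    pats <- learn_patterns(fixture_corpus(20, 60 + s))
    any(pats$template == "术后<TIMEX3>余" & pats$confidence == 1)
  }, logical(1))
  expect_true(all(hits))
})

test_that("learning degenerates gracefully", {
  expect_identical(nrow(learn_patterns(list())), 0L)
  no_ann <- list(timex_document("无标注文本。"))
  expect_identical(nrow(learn_patterns(no_ann)), 0L)
})

test_that("patterns round-trip through the TSV persistence format", {
  pats <- fixture_patterns()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(pats, path)
  back <- read_patterns(path)
  expect_identical(back$template, pats$template)
  expect_equal(back$confidence, pats$confidence)
  expect_identical(as.integer(back$support), pats$support)
})
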