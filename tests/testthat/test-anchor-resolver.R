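# Reference-time resolution: directness, the three strategies, recovery.

test_that("is_direct separates absolute times from anaphoric and duration forms", {
  expect_true(is_direct("2014-10-13", "DATE"))
  expect_true(is_direct("2014年6月", "DATE"))
  expect_true(is_direct("2014/10/11 7:48:16", "TIME"))
  expect_false(is_direct("1周前", "DATE"))
  expect_false(is_direct("22/9", "DATE"))       # year missing
  expect_false(is_direct("一个月", "DURATION")) # DURATION excluded by definition
  expect_false(is_direct("2014-10-13", "DURATION"))
  expect_false(is_direct("目前", "DATE"))
})

# A document exercising all three strategies, mirroring the discharge-summary
# layout: critical event in sentence, section phrase, nearest direct fallback.
strategy_doc <- function(with_discharge = TRUE) {
  dis_line <- if (with_discharge) {
    '出院日期:<TIMEX3 tid="t2" Type="DATE" Value="2014-09-30">2014-09-30</TIMEX3>\n'
  } else "出院日期:出院日期\n"
  read_timeml(paste0(
    '入院日期:<TIMEX3 tid="t1" Type="DATE" Value="2014-09-20">2014-09-20</TIMEX3>\n',
    dis_line,
    '<TIMEX3 tid="t3" Type="DATE" Value="2014-09-22">2014-09-22</TIMEX3>行第一次化疗。\n',
    '出院情况:<TIMEX3 tid="t4" Type="DATE" Value="">目前</TIMEX3>患者情况可。\n',
    '出院医嘱:1、化疗后<TIMEX3 tid="t5" Type="SET" Value="">第7、10、14天</TIMEX3>复查血象;',
    '2、<TIMEX3 tid="t6" Type="DATE" Value="">72小时后</TIMEX3>自行拆除绷带;\n'))
}

test_that("strategies follow the priority critical event > section > nearest direct", {
  doc <- strategy_doc(TRUE)
  txs <- doc$timexes

  set_dec <- resolve_anchor(doc, txs[[5]])    # 第7、10、14天 next to 化疗
  expect_identical(set_dec$strategy, "CRITICAL_EVENT")
  expect_identical(set_dec$anchor_tid, "t3")
  expect_identical(format_iso(set_dec$anchor_value), "2014-09-22")

  hour_dec <- resolve_anchor(doc, txs[[6]])   # 72小时后: no event in sentence
  expect_identical(hour_dec$strategy, "SECTION_PHRASE")
  expect_identical(format_iso(hour_dec$anchor_value), "2014-09-30")

  deictic_dec <- resolve_anchor(doc, txs[[4]])
  expect_identical(deictic_dec$strategy, "SECTION_PHRASE")
  expect_identical(format_iso(deictic_dec$anchor_value), "2014-09-30")

  # without a discharge date the section strategy cannot fire: nearest direct
  doc2 <- strategy_doc(FALSE)
  fallback <- resolve_anchor(doc2, doc2$timexes[[3]])
  expect_identical(fallback$strategy, "NEAREST_DIRECT")
  expect_identical(fallback$anchor_tid, "t3")  # nearest preceding direct
})

test_that("direct mentions and durations need no anchor", {
  doc <- strategy_doc(TRUE)
  dec <- resolve_anchor(doc, doc$timexes[[1]])
  expect_identical(dec$strategy, "NONE")
  expect_false(dec$needs_anchor)
  dur <- timex3("t9", "DURATION", "P1M", 0, 4, "入院日期")  # type decides
  expect_identical(resolve_anchor(doc, dur)$strategy, "NONE")
})

test_that("resolution is pure: re-running gives identical decisions", {
  doc <- strategy_doc(TRUE)
  d1 <- resolve_anchor(doc, doc$timexes[[5]])
  d2 <- resolve_anchor(doc, doc$timexes[[5]])
  expect_identical(d1, d2)
})

test_that("an unresolvable anchor raises a typed condition carrying the tid", {
  doc <- read_timeml('病程中<TIMEX3 tid="t1" Type="DATE" Value="">3天前</TIMEX3>发热。')
  err <- tryCatch(resolve_anchor(doc, doc$timexes[[1]]), condition = identity)
  expect_s3_class(err, "unresolved_anchor")
  expect_identical(err$tid, "t1")
})

test_that("gold anchors are recovered on generated documents", {
  total <- 0L; ok <- 0L
  for (doc in c(fixture_corpus(15, 90), fixture_corpus(15, 91, typo_rate = 1))) {
    dv <- zhtimex:::direct_value_map(doc)
    ctx <- doc_context(doc, direct_values = dv)
    values <- stats::setNames(timex_table(doc)$value, timex_table(doc)$tid)
    for (tx in doc$timexes) {
      if (is.na(tx$anchor_tid)) next
      total <- total + 1L
      dec <- resolve_anchor(doc, tx, direct_values = dv, ctx = ctx)
      if (identical(dec$anchor_tid, tx$anchor_tid) &&
          identical(format_iso(dec$anchor_value), values[[tx$anchor_tid]])) {
        ok <- ok + 1L
      }
    }
  }
  expect_gte(ok / total, 0.99)
})
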