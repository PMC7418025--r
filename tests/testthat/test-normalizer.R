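# Value computation: direct forms, offsets, durations, sets, corrections,
# and the end-to-end annotate pipeline.

test_that("direct absolute forms normalize to their ISO values", {
  expect_identical(format_iso(normalize_direct("2014年6月3日")), "2014-06-03")
  expect_identical(format_iso(normalize_direct("2014年6月")), "2014-06")
  expect_identical(format_iso(normalize_direct("2014年")), "2014")
  expect_identical(format_iso(normalize_direct("2014/10/11 7:48:16")),
                   "2014-10-11T07:48:16")
  expect_identical(format_iso(normalize_direct("2014-10-13")), "2014-10-13")
  expect_identical(format_iso(normalize_direct("2014年6月3日上午7点20分4秒")),
                   "2014-06-03T07:20:04")
  expect_identical(format_iso(normalize_direct("2014年6月3日下午3点")),
                   "2014-06-03T15:00:00")
  expect_error(normalize_direct("22/9"), "unparseable")
})

test_that("relative surfaces parse into magnitude/unit/direction", {
  expect_identical(parse_relative("6天前"),
                   list(magnitude = 6L, unit = "DAY", direction = "BEFORE",
                        approx = FALSE))
  expect_identical(parse_relative("72小时后"),
                   list(magnitude = 72L, unit = "HOUR", direction = "AFTER",
                        approx = FALSE))
  expect_identical(parse_relative("两周后")$magnitude, 2L)
  expect_identical(parse_relative("3月余前")$approx, TRUE)
  expect_identical(parse_relative("目前")$direction, "SAME")
  expect_error(parse_relative("前"), "not a relative")
})

test_that("offsets reproduce the documented normalizations", {
  ref <- parse_iso("2014-10-23")
  expect_identical(format_iso(apply_offset(ref, parse_relative("6天前"))),
                   "2014-10-17")
  expect_identical(format_iso(apply_offset(parse_iso("2014-08-09"),
                                           parse_relative("1周前"))),
                   "2014-08-02")
  # 72 hours against a date-only reference floors to whole days
  expect_identical(format_iso(apply_offset(parse_iso("2014-09-30"),
                                           parse_relative("72小时后"))),
                   "2014-10-03")
  # month arithmetic clamps the day of month
  expect_identical(format_iso(apply_offset(parse_iso("2014-03-31"),
                                           parse_relative("1月前"))),
                   "2014-02-28")
  # SAME returns the reference unchanged
  expect_identical(format_iso(apply_offset(ref, parse_relative("目前"))),
                   "2014-10-23")
})

test_that("offset arithmetic agrees with the independent calendar oracle", {
  set.seed(21)
  for (i in 1:100) {
    d <- as.Date("2012-01-01") + sample(0:2000, 1)
    ref <- parse_iso(format(d, "%Y-%m-%d"))
    n <- sample(1:30, 1)
    expect_identical(
      format_iso(apply_offset(ref, list(magnitude = n, unit = "DAY",
                                        direction = "AFTER", approx = FALSE))),
      oracle_shift_days(format(d), n))
    m <- sample(1:24, 1)
    expect_identical(
      format_iso(apply_offset(ref, list(magnitude = m, unit = "MONTH",
                                        direction = "BEFORE", approx = FALSE))),
      oracle_shift_months(format(d), -m))
  }
})

test_that("BEFORE/AFTER offsets are involutions on uniform units", {
  set.seed(22)
  for (i in 1:50) {
    ref <- parse_iso(format(as.Date("2013-01-01") + sample(0:1500, 1)))
    n <- sample(1:20, 1)
    unit <- sample(c("DAY", "WEEK"), 1)
    back <- apply_offset(ref, list(magnitude = n, unit = unit,
                                   direction = "BEFORE", approx = FALSE))
    there <- apply_offset(back, list(magnitude = n, unit = unit,
                                     direction = "AFTER", approx = FALSE))
    expect_identical(format_iso(there), format_iso(ref))
  }
})

test_that("insufficient reference precision raises an error", {
  expect_error(apply_offset(parse_iso("2014-06"), parse_relative("3天前")),
               "precision")
  expect_error(apply_offset(parse_iso("2014"), parse_relative("2月后")),
               "precision")
})

test_that("durations normalize with approximation markers dropped", {
  expect_identical(format_iso(normalize_duration("两年五个月")), "P2Y5M")
  expect_identical(format_iso(normalize_duration("1年余")), "P1Y")
  expect_identical(format_iso(normalize_duration("一个月")), "P1M")
  expect_identical(format_iso(normalize_duration("2周")), "P2W")
  expect_identical(format_iso(normalize_duration("72小时")), "PT72H")
  expect_error(normalize_duration("无穷"), "unparseable")
})

test_that("day sets count the event day as day 1", {
  expect_identical(format_iso(normalize_set("第1天", parse_iso("2014-09-22"))),
                   "[2014-09-22]")
  expect_identical(format_iso(normalize_set("第7、10、14天", parse_iso("2014-09-01"))),
                   "[2014-09-07,2014-09-10,2014-09-14]")
  expect_identical(format_iso(normalize_set("第2、3天", parse_iso("2014-12-31"))),
                   "[2015-01-01,2015-01-02]")
  expect_error(normalize_set("第2、3天", NULL), "reference")
})

correction_doc <- function() {
  read_timeml(paste0(
    '于<TIMEX3 tid="t1" Type="DATE" Value="2014-06-10">2014年6月10日</TIMEX3>行手术。',
    '主诉:右乳腺癌术后<TIMEX3 tid="t2" Type="DATE" Value="" anchorTimeID="t1">3月</TIMEX3>余,返院行化疗。'))
}

test_that("a matching anchor-equality pattern overrides the computed value", {
  doc <- correction_doc()
  pats <- data.frame(template = "术后<TIMEX3>余", purpose = "NORM_ANCHOR_EQUALS",
                     support = 20L, confidence = 1, stringsAsFactors = FALSE)
  out <- normalize_document(doc, pats)
  expect_identical(out$timexes[[2]]$value, "2014-06-10")  # reference value
  # without the pattern the month reference resolves within the anchor year
  out2 <- normalize_document(doc, NULL)
  expect_identical(out2$timexes[[2]]$value, "2014-03")
})

test_that("the documented pattern mis-fire is reproduced", {
  doc <- read_timeml(paste0(
    '于<TIMEX3 tid="t1" Type="DATE" Value="2014-10-23">2014-10-23</TIMEX3>入院。',
    '<TIMEX3 tid="t2" Type="DATE" Value="" anchorTimeID="t1">6天前</TIMEX3>于我院行双乳B超。'))
  mis <- data.frame(template = "<TIMEX3>于我", purpose = "NORM_ANCHOR_EQUALS",
                    support = 5L, confidence = 0.9, stringsAsFactors = FALSE)
  out <- normalize_document(doc, mis)
  # the over-general context overrides the (correct) offset value 2014-10-17
  expect_identical(out$timexes[[2]]$value, "2014-10-23")
  out2 <- normalize_document(doc, NULL)
  expect_identical(out2$timexes[[2]]$value, "2014-10-17")
})

test_that("annotate handles single-mention and mention-free documents", {
  model <- fixture_model()
  doc <- annotate("2014-10-13", model)
  expect_length(doc$timexes, 1)
  expect_identical(doc$timexes[[1]]$tid, "t1")
  expect_identical(doc$timexes[[1]]$ttype, "DATE")
  expect_identical(doc$timexes[[1]]$value, "2014-10-13")

  none <- annotate("查体未见异常。", model)
  expect_length(none$timexes, 0)
  expect_identical(none$text, "查体未见异常。")
})

test_that("annotation is deterministic and idempotent on its own text", {
  model <- fixture_model()
  pats <- fixture_patterns()
  doc <- fixture_corpus(3, 95)[[2]]
  a1 <- suppressWarnings(annotate(doc$text, model, pats))
  a2 <- suppressWarnings(annotate(a1$text, model, pats))
  expect_identical(timex_table(a1), timex_table(a2))
  expect_identical(a1$text, doc$text)
})

test_that("per-mention failures warn and leave an empty Value", {
  model <- fixture_model()
  # a relative mention with no resolvable reference anywhere
  expect_warning(doc <- annotate("病程中3天前发热。", model), "reference")
  expect_length(doc$timexes, 1)
  expect_identical(doc$timexes[[1]]$value, "")
})
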