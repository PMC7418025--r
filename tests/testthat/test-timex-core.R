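# ISO 8601 value codec and inline-TimeML document model.

test_that("parse_iso handles the documented value shapes", {
  d <- parse_iso("P2Y5M")
  expect_identical(d$kind, "duration")
  expect_identical(d$years, 2L)
  expect_identical(d$months, 5L)
  expect_identical(d$days, 0L)

  y <- parse_iso("2014")
  expect_identical(y$kind, "date")
  expect_true(is.na(y$month))

  t <- parse_iso("2014-06-03T07:20:04")
  expect_identical(t$kind, "time")
  expect_identical(c(t$hour, t$minute, t$second), c(7L, 20L, 4L))
  expect_identical(format_iso(t$date), "2014-06-03")

  # lenient about unpadded fields, strict about nonsense
  expect_identical(format_iso(parse_iso("2014-6-3")), "2014-06-03")
  expect_error(parse_iso("2014-13"), "month")
  expect_error(parse_iso("2014-02-30"), "day")
  expect_error(parse_iso("P"), "duration")
  expect_error(parse_iso("banana"), "malformed")
  expect_error(parse_iso(""), "non-empty")
})

test_that("format_iso canonicalizes: padding, zero omission, week handling", {
  expect_identical(format_iso(iso_date(2014, 6, 3)), "2014-06-03")
  expect_identical(format_iso(iso_date(2014, 6)), "2014-06")
  expect_identical(format_iso(iso_date(2014)), "2014")
  expect_identical(format_iso(iso_duration(months = 1)), "P1M")
  expect_identical(format_iso(iso_duration(years = 2, months = 5)), "P2Y5M")
  expect_identical(format_iso(iso_duration(weeks = 2)), "P2W")
  # weeks mixed with other units convert to days (no mixed W designator)
  expect_identical(format_iso(iso_duration(weeks = 1, days = 1)), "P8D")
  expect_identical(format_iso(iso_duration(hours = 72)), "PT72H")
  expect_identical(
    format_iso(iso_dateset(list(iso_date(2014, 9, 7), iso_date(2014, 9, 10)))),
    "[2014-09-07,2014-09-10]")
})

test_that("parse_iso . format_iso is the identity on random values", {
  set.seed(42)
  for (i in 1:200) {
    v <- random_iso_value()
    s <- format_iso(v)
    expect_identical(format_iso(parse_iso(s)), s)
  }
})

test_that("read_timeml parses annotated examples with spans over stripped text", {
  doc <- read_timeml(paste0(
    '<TIMEX3 tid="t1" Type="TIME" Value="2014-10-11T07:48:16">',
    "2014/10/11 7:48:16</TIMEX3>"))
  expect_length(doc$timexes, 1)
  tx <- doc$timexes[[1]]
  expect_identical(tx$ttype, "TIME")
  expect_identical(tx$surface, "2014/10/11 7:48:16")
  expect_identical(c(tx$begin, tx$end), c(0L, 18L))
  expect_identical(doc$text, "2014/10/11 7:48:16")

  doc2 <- read_timeml(paste0(
    '入院<TIMEX3 tid="t2" Type="DATE" Value="2014-08-09">2014-08-09</TIMEX3>,',
    '<TIMEX3 tid="t7" Type="DATE" Value="2014-08-02" anchorTimeID="t2">1 周前</TIMEX3>发病'))
  expect_identical(doc2$timexes[[2]]$anchor_tid, "t2")
  expect_identical(doc2$timexes[[2]]$surface, "1 周前")

  plain <- read_timeml("no markup at all")
  expect_length(plain$timexes, 0)
  expect_identical(plain$text, "no markup at all")
})

test_that("read_timeml rejects malformed annotation with an offset", {
  expect_error(read_timeml('a<TIMEX3 tid="t1" Type="DATE" Value="2014">x'),
               "unclosed.*offset")
  expect_error(read_timeml(paste0(
    '<TIMEX3 tid="t1" Type="DATE" Value="2014">x</TIMEX3>',
    '<TIMEX3 tid="t1" Type="DATE" Value="2015">y</TIMEX3>')),
    "duplicate tid")
  expect_error(read_timeml('<TIMEX3 tid="t1" Type="EPOCH" Value="2014">x</TIMEX3>'),
               "unknown Type")
  expect_error(read_timeml('<TIMEX3 tid="t1" Type="DATE">x</TIMEX3>'),
               "missing required attribute")
})

test_that("write_timeml round-trips documents, including generated ones", {
  doc <- read_timeml(paste0(
    "既往<TIMEX3 tid=\"t4\" Type=\"DURATION\" Value=\"P1Y\">1年余</TIMEX3>"))
  out <- write_timeml(doc)
  expect_match(out, '<TIMEX3 tid="t4" Type="DURATION" Value="P1Y">1年余</TIMEX3>',
               fixed = TRUE)

  empty <- timex_document("就诊经过如常。")
  expect_identical(write_timeml(empty), "就诊经过如常。")

  for (doc in fixture_corpus(5, 123)) {
    rt <- read_timeml(write_timeml(doc), doc_id = doc$doc_id)
    expect_identical(rt$text, doc$text)
    expect_identical(timex_table(rt), timex_table(doc))
  }

  set.seed(9)
  for (i in 1:20) {
    doc <- random_document(sample(1:4, 1))
    rt <- read_timeml(write_timeml(doc))
    expect_identical(timex_table(rt), timex_table(doc))
  }
})

test_that("document invariants are enforced", {
  txt <- "甲2014乙"
  expect_error(timex3("x1", "DATE", "2014", 0, 4, "2014"), "bad tid")
  expect_error(timex3("t1", "YEAR", "2014", 0, 4, "2014"), "unknown Type")
  bad_surface <- timex_document(txt, list(timex3("t1", "DATE", "2014", 0, 4, "2014")))
  expect_error(validate_document(bad_surface), "surface")
  overlapping <- timex_document("20142015", list(
    timex3("t1", "DATE", "2014", 0, 5, "20142"),
    timex3("t2", "DATE", "2015", 3, 8, "42015")))
  expect_error(validate_document(overlapping), "overlap")
  dangling <- timex_document(txt, list(
    timex3("t1", "DATE", "2014", 1, 5, "2014", anchor_tid = "t9")))
  expect_error(validate_document(dangling), "unknown tid")
})
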