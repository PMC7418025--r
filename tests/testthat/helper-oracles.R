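# Shared fixtures and independent oracles for the test suite.

PH <- "<TIMEX3>"

# --- independent calendar oracle (lubridate) --------------------------------

oracle_shift_months <- function(date_str, delta) {
  # month arithmetic with day-of-month rollback, independent of the package
  format(lubridate::add_with_rollback(as.Date(date_str), months(delta)),
         "%Y-%m-%d")
}

oracle_shift_days <- function(date_str, delta) {
  format(as.Date(date_str) + delta, "%Y-%m-%d")
}

# --- brute-force substring enumeration oracle -------------------------------

# All distinct contiguous token substrings containing exactly one placeholder,
# of token length <= max_len.
oracle_enumerate <- function(templated, max_len) {
  parts <- strsplit(templated, PH, fixed = TRUE)[[1]]
  n_ph <- (nchar(templated) - nchar(gsub(PH, "", templated, fixed = TRUE))) /
    nchar(PH)
  toks <- character(0)
  if (length(parts) == 0) parts <- ""
  for (i in seq_along(parts)) {
    if (nzchar(parts[i])) toks <- c(toks, strsplit(parts[i], "")[[1]])
    if (i <= n_ph) toks <- c(toks, PH)
  }
  while (sum(toks == PH) < n_ph) toks <- c(toks, PH)
  out <- character(0)
  for (a in seq_along(toks)) {
    for (b in a:min(length(toks), a + max_len - 1)) {
      window <- toks[a:b]
      if (sum(window == PH) == 1) out <- c(out, paste0(window, collapse = ""))
    }
  }
  unique(out)
}

# Random templated strings over a small alphabet with 1-2 placeholders.
random_templated <- function(n_chars, n_ph = 1) {
  alpha <- c("甲", "乙", "丙", "丁", "a", "b")
  toks <- sample(alpha, n_chars, replace = TRUE)
  at <- sort(sample(seq_len(n_chars + n_ph), n_ph))
  for (i in seq_along(at)) toks <- append(toks, PH, after = at[i] - 1 + (i - 1))
  paste0(toks, collapse = "")
}

# --- random value / document generators -------------------------------------

random_iso_value <- function() {
  kind <- sample(c("date", "time", "duration", "set"), 1)
  rdate <- function() {
    y <- sample(1990:2030, 1)
    prec <- sample(1:3, 1)
    if (prec == 1) return(iso_date(y))
    m <- sample(1:12, 1)
    if (prec == 2) return(iso_date(y, m))
    iso_date(y, m, sample(1:28, 1))
  }
  switch(kind,
    date = rdate(),
    time = iso_time(iso_date(sample(1990:2030, 1), sample(1:12, 1),
                             sample(1:28, 1)),
                    sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)),
    duration = {
      comp <- stats::rbinom(7, 1, 0.3) * sample(1:30, 7, replace = TRUE)
      if (sum(comp) == 0) comp[sample(1:7, 1)] <- sample(1:30, 1)
      iso_duration(comp[1], comp[2], comp[3], comp[4], comp[5], comp[6], comp[7])
    },
    set = iso_dateset(lapply(seq_len(sample(1:4, 1)), function(i) {
      iso_date(2014, sample(1:12, 1), sample(1:28, 1))
    }))
  )
}

random_document <- function(n_tes = 3) {
  pieces <- c("")
  txs <- list()
  pos <- 0L
  filler <- c("患者", "复查", "。", "血象良好", ",", "门诊随诊")
  for (i in seq_len(n_tes)) {
    pre <- paste0(sample(filler, sample(1:3, 1), replace = TRUE), collapse = "")
    surface <- sample(c("2014-10-13", "目前", "3天前", "1年余", "第2、3天"), 1)
    value <- format_iso(random_iso_value())
    pieces <- c(pieces, pre, surface)
    pos <- pos + nchar(pre)
    txs[[i]] <- timex3(paste0("t", i), sample(c("DATE", "TIME", "DURATION", "SET"), 1),
                       value, pos, pos + nchar(surface), surface)
    pos <- pos + nchar(surface)
  }
  pieces <- c(pieces, "。")
  timex_document(paste0(pieces, collapse = ""), txs, doc_id = "rand")
}

# --- shared trained fixtures (memoised across test files) -------------------

.fixture_env <- new.env(parent = emptyenv())

fixture_corpus <- function(n_docs = 40, seed = 7, ...) {
  key <- paste0("corpus_", n_docs, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_corpus(gen_config(n_docs = n_docs,
                                                      seed = seed, ...))
  }
  .fixture_env[[key]]
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- fit_type_classifier(
      corpus_vectors(fixture_corpus(40, 7)), classifier_config(seed = 7))
  }
  .fixture_env$model
}

fixture_patterns <- function() {
  if (is.null(.fixture_env$patterns)) {
    .fixture_env$patterns <- learn_patterns(fixture_corpus(40, 7))
  }
  .fixture_env$patterns
}

# three-document miner fixture with hand-countable pattern statistics
miner_fixture <- function() {
  list(
    read_timeml(paste0(
      '于<TIMEX3 tid="t1" Type="DATE" Value="2014-01-05">2014-01-05</TIMEX3>行手术。',
      '术后<TIMEX3 tid="t2" Type="DATE" Value="2014-01-05" anchorTimeID="t1">2月</TIMEX3>余复查。'),
      doc_id = "fixA"),
    read_timeml(paste0(
      '于<TIMEX3 tid="t1" Type="DATE" Value="2014-02-03">2014-02-03</TIMEX3>行手术。',
      '术后<TIMEX3 tid="t2" Type="DATE" Value="2014-03-03" anchorTimeID="t1">1月</TIMEX3>余复查。'),
      doc_id = "fixB"),
    read_timeml(
      '术后<TIMEX3 tid="t1" Type="DURATION" Value="P3D">3天</TIMEX3>出现疼痛。',
      doc_id = "fixC")
  )
}
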