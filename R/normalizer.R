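# Value normalization: direct absolute times, relative offsets against a
# reference time, durations, day sets, anchor-equality corrections from
# learned patterns, and the end-to-end annotate pipeline.

UNIT_MAP <- c(
  "年" = "YEAR", "月" = "MONTH", "个月" = "MONTH", "周" = "WEEK",
  "星期" = "WEEK", "天" = "DAY", "日" = "DAY", "小时" = "HOUR",
  "个小时" = "HOUR", "时" = "HOUR", "分钟" = "MINUTE", "秒" = "SECOND"
)

NUM_RE <- "(?:[0-9]+|[一二三四五六七八九十两零]+)"
DEICTIC_RE <- "^(?:目前|现在|现|今天|今晨|今日|今|入院时|出院时)$"

#' Normalize a direct (absolute) temporal expression
#'
#' Parses complete absolute dates and datetimes: 2014年6月3日 / 2014年6月 /
#' 2014年 / 2014-06-03 / 2014/6/3 / 2014/10/11 7:48:16 /
#' 2014年6月3日上午7点20分4秒. Afternoon/evening day-part words add 12 hours.
#'
#' @param surface a surface for which [is_direct()] holds.
#' @param ttype predicted type (unused for parsing, kept for symmetry).
#' @return an `iso_value`.
#' @export
normalize_direct <- function(surface, ttype = "DATE") {
  s <- gsub("[[:space:]]+", " ", trimws(surface))
  m <- regmatches(s, regexec(
    "^([0-9]{4})年(?:([0-9]{1,2})月(?:([0-9]{1,2})日)?)? ?(上午|下午|凌晨|晚)? ?(?:([0-9]{1,2})[点时](?:([0-9]{1,2})分(?:([0-9]{1,2})秒)?)?)?$", s))[[1]]
  if (length(m) > 0) {
    d <- iso_date(as.integer(m[2]),
                  if (nzchar(m[3])) as.integer(m[3]) else NA,
                  if (nzchar(m[4])) as.integer(m[4]) else NA)
    if (!nzchar(m[6])) return(d)
    hour <- as.integer(m[6])
    if (m[5] %in% c("下午", "晚") && hour < 12) hour <- hour + 12L
    return(iso_time(d, hour,
                    if (nzchar(m[7])) as.integer(m[7]) else 0L,
                    if (nzchar(m[8])) as.integer(m[8]) else 0L))
  }
  m <- regmatches(s, regexec(
    "^([0-9]{4})[/-]([0-9]{1,2})(?:[/-]([0-9]{1,2}))?(?:[ T]([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?)?$", s))[[1]]
  if (length(m) > 0) {
    d <- iso_date(as.integer(m[2]), as.integer(m[3]),
                  if (nzchar(m[4])) as.integer(m[4]) else NA)
    if (!nzchar(m[5])) return(d)
    return(iso_time(d, as.integer(m[5]), as.integer(m[6]),
                    if (nzchar(m[7])) as.integer(m[7]) else 0L))
  }
  stop(sprintf("normalize_direct: unparseable absolute expression '%s'", surface))
}

#' Parse a relative temporal expression
#'
#' Converts Chinese numerals, maps 前/后 to BEFORE/AFTER and deictics
#' (目前 现在 今天 入院时 出院时 ...) to SAME; 余/约/多 set the `approx` flag.
#'
#' @param surface a relative or deictic surface, e.g. "6天前", "72小时后".
#' @return list(magnitude, unit, direction, approx) with unit one of YEAR,
#'   MONTH, WEEK, DAY, HOUR, MINUTE, SECOND and direction BEFORE/AFTER/SAME.
#' @export
parse_relative <- function(surface) {
  s <- gsub("[[:space:]]+", "", surface)
  if (grepl(DEICTIC_RE, s)) {
    return(list(magnitude = 0L, unit = "DAY", direction = "SAME", approx = FALSE))
  }
  m <- regmatches(s, regexec(paste0(
    "^(", NUM_RE, ")(个月|个小时|小时|分钟|星期|年|月|周|天|日|时|秒)([余约多]?)([前后])$"), s,
    perl = TRUE))[[1]]
  if (length(m) == 0) {
    stop(sprintf("parse_relative: not a relative expression '%s'", surface))
  }
  mag <- zh_numeral(m[2])
  if (is.na(mag) || mag < 1) {
    stop(sprintf("parse_relative: bad magnitude in '%s'", surface))
  }
  list(magnitude = mag, unit = unname(UNIT_MAP[m[3]]),
       direction = if (m[5] == "前") "BEFORE" else "AFTER",
       approx = nzchar(m[4]))
}

# Month arithmetic with day-of-month clamping.
shift_months <- function(year, month, day, delta) {
  total <- (year * 12L + (month - 1L)) + delta
  y <- total %/% 12L
  mo <- total %% 12L + 1L
  if (is.na(day)) return(iso_date(y, mo))
  iso_date(y, mo, min(day, days_in_month(y, mo)))
}

#' Apply a relative offset to a reference time
#'
#' Calendar-aware arithmetic: month offsets clamp the day of month; week
#' offsets are seven days; hour/minute/second offsets against a date-only
#' reference floor to whole days; SAME returns the reference unchanged. The
#' `approx` flag ("more than") does not change the value. Output precision
#' follows the reference, except that month/year offsets against coarser
#' references stay at the reference's precision.
#'
#' @param reference an `iso_value` date or time. Day precision is required for
#'   DAY/WEEK/HOUR/MINUTE/SECOND offsets, month precision for MONTH, year for
#'   YEAR.
#' @param spec a [parse_relative()] result.
#' @return an `iso_value`.
#' @export
apply_offset <- function(reference, spec) {
  stopifnot(inherits(reference, "iso_value"))
  if (spec$direction == "SAME") return(reference)
  sign <- if (spec$direction == "BEFORE") -1L else 1L
  ref_date <- if (reference$kind == "time") reference$date else reference
  if (ref_date$kind != "date") stop("apply_offset: reference must be a date or time")
  prec <- iso_precision(ref_date)
  need <- switch(spec$unit, YEAR = "year", MONTH = "month", "day")
  rank <- c(year = 1L, month = 2L, day = 3L)
  if (rank[prec] < rank[need]) {
    stop(sprintf("apply_offset: reference precision '%s' insufficient for %s offset",
                 prec, spec$unit))
  }
  switch(spec$unit,
    YEAR = iso_date(ref_date$year + sign * spec$magnitude, ref_date$month,
                    if (is.na(ref_date$month)) NA else
                      if (is.na(ref_date$day)) NA else
                        min(ref_date$day,
                            days_in_month(ref_date$year + sign * spec$magnitude,
                                          ref_date$month))),
    MONTH = shift_months(ref_date$year, ref_date$month, ref_date$day,
                         sign * spec$magnitude),
    WEEK = Date_to_iso(iso_to_Date(ref_date) + sign * 7L * spec$magnitude),
    DAY = Date_to_iso(iso_to_Date(ref_date) + sign * spec$magnitude),
    HOUR = ,
    MINUTE = ,
    SECOND = {
      secs <- spec$magnitude * switch(spec$unit, HOUR = 3600, MINUTE = 60, SECOND = 1)
      if (reference$kind == "time") {
        t0 <- as.POSIXct(sprintf("%s %02d:%02d:%02d",
                                 format(iso_to_Date(ref_date)),
                                 reference$hour, reference$minute,
                                 reference$second), tz = "UTC")
        t1 <- as.POSIXlt(t0 + sign * secs, tz = "UTC")
        iso_time(iso_date(t1$year + 1900L, t1$mon + 1L, t1$mday),
                 t1$hour, t1$min, as.integer(t1$sec))
      } else {
        Date_to_iso(iso_to_Date(ref_date) + sign * (secs %/% 86400))
      }
    })
}

#' Normalize a duration expression
#'
#' 两年五个月 -> P2Y5M; approximation markers (余 约 多) are dropped; pure-week
#' durations stay weeks (P2W).
#'
#' @param surface a DURATION-typed surface.
#' @return an `iso_value` duration.
#' @export
normalize_duration <- function(surface) {
  s <- gsub("[[:space:]]+|[余约多]", "", surface)
  piece_re <- paste0("(", NUM_RE, ")(个月|个小时|小时|分钟|星期|年|月|周|天|日|时|秒)")
  m <- gregexpr(piece_re, s, perl = TRUE)
  if (m[[1]][1] == -1) stop(sprintf("normalize_duration: unparseable '%s'", surface))
  pieces <- regmatches(s, m)[[1]]
  if (paste0(pieces, collapse = "") != s) {
    stop(sprintf("normalize_duration: unparseable '%s'", surface))
  }
  comp <- c(YEAR = 0L, MONTH = 0L, WEEK = 0L, DAY = 0L, HOUR = 0L,
            MINUTE = 0L, SECOND = 0L)
  for (p in pieces) {
    pm <- regmatches(p, regexec(piece_re, p, perl = TRUE))[[1]]
    unit <- unname(UNIT_MAP[pm[3]])
    comp[unit] <- comp[unit] + zh_numeral(pm[2])
  }
  iso_duration(comp["YEAR"], comp["MONTH"], comp["WEEK"], comp["DAY"],
               comp["HOUR"], comp["MINUTE"], comp["SECOND"])
}

#' Normalize an enumerated day set
#'
#' 第k天 counts the event day as day 1, so each ordinal k maps to
#' reference + (k - 1) days.
#'
#' @param surface a SET-typed surface, e.g. "第7、10、14天".
#' @param reference a day-precise `iso_value`.
#' @return an `iso_value` date set.
#' @export
normalize_set <- function(surface, reference) {
  if (is.null(reference)) stop(unresolved_anchor("(set)"))
  s <- gsub("[[:space:]]+", "", surface)
  m <- regmatches(s, regexec(paste0(
    "^第(", NUM_RE, "(?:[、,，]", NUM_RE, ")*)天$"), s, perl = TRUE))[[1]]
  if (length(m) == 0) stop(sprintf("normalize_set: unparseable '%s'", surface))
  ks <- vapply(strsplit(m[2], "[、,，]")[[1]], zh_numeral, integer(1))
  if (anyNA(ks) || any(ks < 1)) stop(sprintf("normalize_set: bad ordinal in '%s'", surface))
  ref <- iso_to_Date(reference)
  iso_dateset(lapply(ks, function(k) Date_to_iso(ref + (k - 1L))))
}

# Month-reference surfaces ("2月", "3月", optionally 日): the year (and for
# D/M slash forms the whole frame) comes from the reference time.
normalize_partial <- function(surface, reference) {
  ref_date <- if (reference$kind == "time") reference$date else reference
  s <- gsub("[[:space:]]+", "", surface)
  m <- regmatches(s, regexec("^([0-9]{1,2})月(?:([0-9]{1,2})日)?$", s))[[1]]
  if (length(m) > 0) {
    return(iso_date(ref_date$year, as.integer(m[2]),
                    if (nzchar(m[3])) as.integer(m[3]) else NA))
  }
  m <- regmatches(s, regexec("^([0-9]{1,2})/([0-9]{1,2})$", s))[[1]]
  if (length(m) > 0) {   # D/M convention: 22/9 is the 22nd of September
    return(iso_date(ref_date$year, as.integer(m[3]), as.integer(m[2])))
  }
  stop(sprintf("normalize_partial: unparseable '%s'", surface))
}

#' Apply anchor-equality correction patterns
#'
#' If any learned NORM_ANCHOR_EQUALS template matches the mention's context
#' (placeholder at the mention's span), the normalized value is overridden
#' with the anchor's value; the longest matching template wins.
#'
#' @param doc the `timex_document` being annotated.
#' @param tx the mention (must have a resolved anchor value).
#' @param patterns pattern data.frame; only NORM_ANCHOR_EQUALS rows are used.
#' @param anchor_value the mention's resolved reference `iso_value`.
#' @return the override `iso_value`, or `NULL` when no pattern matches.
#' @export
apply_correction <- function(doc, tx, patterns, anchor_value) {
  if (is.null(patterns) || nrow(patterns) == 0 || is.null(anchor_value)) {
    return(NULL)
  }
  pats <- patterns[patterns$purpose == "NORM_ANCHOR_EQUALS", , drop = FALSE]
  if (nrow(pats) == 0) return(NULL)
  pats <- pats[order(-nchar(pats$template)), , drop = FALSE]
  for (i in seq_len(nrow(pats))) {
    ctx <- split_template(pats$template[i])
    left_ok <- !nzchar(ctx$left) ||
      identical(slice(doc$text, max(0L, tx$begin - nchar(ctx$left)), tx$begin),
                ctx$left)
    right_ok <- !nzchar(ctx$right) ||
      identical(slice(doc$text, tx$end,
                      min(nchar(doc$text), tx$end + nchar(ctx$right))),
                ctx$right)
    if (left_ok && right_ok) return(anchor_value)
  }
  NULL
}

#' Annotate a raw clinical document end to end
#'
#' extract -> classify -> resolve anchors (direct mentions first, anaphoric in
#' document order) -> normalize -> correct. Per-mention failures are recorded
#' as warnings and the mention is emitted with an empty Value rather than
#' aborting the document.
#'
#' @param text raw document text (UTF-8, markup-free).
#' @param model a fitted `type_model`.
#' @param patterns learned pattern data.frame (NORM_ANCHOR_EQUALS rows correct
#'   values; EXTRACTION rows may add spans). `NULL` for rules only.
#' @param lexicons anchor lexicons.
#' @param rules extraction rule set.
#' @param doc_id document identifier.
#' @param tagger,triggers feature extraction ports.
#' @return an annotated `timex_document`.
#' @export
annotate <- function(text, model, patterns = NULL, lexicons = load_lexicons(),
                     rules = load_rules(), doc_id = "doc",
                     tagger = default_tagger(), triggers = load_triggers()) {
  spans <- extract_spans(text, rules, patterns)
  doc <- timex_document(text, list(), doc_id = doc_id)
  if (nrow(spans) == 0) return(doc)
  vecs <- lapply(spans$surface, build_vector, tagger = tagger,
                 triggers = triggers)
  types <- predict_types(model, vecs)
  doc$timexes <- lapply(seq_len(nrow(spans)), function(i) {
    timex3(tid = paste0("t", i), ttype = types[i], value = "",
           begin = spans$begin[i], end = spans$end[i],
           surface = spans$surface[i])
  })
  normalize_document(doc, patterns, lexicons)
}

#' Normalize the mentions of a typed document
#'
#' The normalization stage on its own: direct mentions first, then anaphoric
#' mentions in document order with anchor resolution and pattern correction.
#' Used by [annotate()] and, on gold spans with predicted types, by the
#' accuracy evaluation.
#'
#' @param doc `timex_document` whose mentions carry (predicted) types.
#' @param patterns pattern data.frame or `NULL`.
#' @param lexicons anchor lexicons.
#' @return the document with values (and anchor tids) filled in.
#' @export
normalize_document <- function(doc, patterns = NULL, lexicons = load_lexicons()) {
  # pass 1: direct mentions
  for (i in seq_along(doc$timexes)) {
    tx <- doc$timexes[[i]]
    if (is_direct(tx$surface, tx$ttype)) {
      v <- tryCatch(normalize_direct(tx$surface, tx$ttype), error = warn_skip(tx))
      if (!is.null(v)) doc$timexes[[i]]$value <- format_iso(v)
    } else if (tx$ttype == "DURATION") {
      v <- tryCatch(normalize_duration(tx$surface), error = warn_skip(tx))
      if (!is.null(v)) doc$timexes[[i]]$value <- format_iso(v)
    }
  }
  direct_values <- direct_value_map(doc)
  ctx <- doc_context(doc, lexicons, direct_values)
  # pass 2: anaphoric mentions in document order
  for (i in seq_along(doc$timexes)) {
    tx <- doc$timexes[[i]]
    if (nzchar(doc$timexes[[i]]$value)) next
    res <- tryCatch({
      dec <- resolve_anchor(doc, tx, lexicons, direct_values, ctx)
      v <- normalize_anaphoric(tx, dec$anchor_value)
      corr <- apply_correction(doc, tx, patterns, dec$anchor_value)
      if (!is.null(corr)) v <- corr
      list(value = v, anchor_tid = dec$anchor_tid)
    }, error = warn_skip(tx))
    if (!is.null(res)) {
      doc$timexes[[i]]$value <- format_iso(res$value)
      if (!is.na(res$anchor_tid)) doc$timexes[[i]]$anchor_tid <- res$anchor_tid
    }
  }
  doc
}

warn_skip <- function(tx) {
  force(tx)
  function(e) {
    warning(sprintf("[%s '%s'] %s", tx$tid, tx$surface, conditionMessage(e)),
            call. = FALSE)
    NULL
  }
}

# Value of a non-direct mention given its resolved reference time.
normalize_anaphoric <- function(tx, anchor_value) {
  if (is.null(anchor_value)) stop(unresolved_anchor(tx$tid))
  if (tx$ttype == "SET") return(normalize_set(tx$surface, anchor_value))
  s <- gsub("[[:space:]]+", "", tx$surface)
  if (grepl(DEICTIC_RE, s)) return(anchor_value)
  if (grepl("^[0-9]{1,2}月(?:[0-9]{1,2}日)?$|^[0-9]{1,2}/[0-9]{1,2}$", s)) {
    return(normalize_partial(tx$surface, anchor_value))
  }
  apply_offset(anchor_value, parse_relative(tx$surface))
}
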