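# TIMEX3 mentions, documents, and the inline-TimeML reader/writer.
#
# Spans are 0-based half-open character intervals over the markup-stripped
# document text. Only the <TIMEX3> tag of the TimeML vocabulary is handled.

TIMEX_TYPES <- c("DATE", "TIME", "DURATION", "SET")

EVENT_KINDS <- c("ADMISSION", "DISCHARGE", "SURGERY", "CHEMOTHERAPY", "RETURN")

# Structured-header lines that carry a document-level event date.
HEADER_LINE_EVENTS <- c(
  "入院日期" = "ADMISSION",   # 入院日期
  "出院日期" = "DISCHARGE"    # 出院日期
)

#' Construct a TIMEX3 mention
#'
#' @param tid identifier string matching `^t[1-9][0-9]*$`.
#' @param ttype one of DATE, TIME, DURATION, SET.
#' @param value ISO 8601 value string (may be empty when normalization failed).
#' @param begin,end 0-based half-open span over the document text.
#' @param surface the exact source substring at the span.
#' @param anchor_tid optional tid of the reference-time mention.
#' @return a `timex3` object.
#' @export
timex3 <- function(tid, ttype, value, begin, end, surface, anchor_tid = NA_character_) {
  if (!grepl("^t[1-9][0-9]*$", tid)) stop(sprintf("timex3: bad tid '%s'", tid))
  if (!ttype %in% TIMEX_TYPES) stop(sprintf("timex3: unknown Type '%s'", ttype))
  begin <- as.integer(begin); end <- as.integer(end)
  if (is.na(begin) || is.na(end) || begin < 0 || end <= begin) {
    stop(sprintf("timex3 %s: invalid span [%s,%s)", tid, begin, end))
  }
  structure(list(tid = tid, ttype = ttype, value = as.character(value),
                 anchor_tid = anchor_tid, begin = begin, end = end,
                 surface = surface),
            class = "timex3")
}

#' Construct a temporal-expression document
#'
#' @param text markup-free document text.
#' @param timexes list of `timex3`, ordered by span begin, non-overlapping.
#' @param doc_id document identifier.
#' @param header_events named list of event kind -> `iso_value` (or omitted)
#'   for dates carried by structured header lines; computed from the text when
#'   `NULL`.
#' @return a `timex_document`.
#' @export
timex_document <- function(text, timexes = list(), doc_id = "doc",
                           header_events = NULL) {
  if (is.null(header_events)) header_events <- scan_header_events(text)
  doc <- structure(list(doc_id = doc_id, text = text, timexes = timexes,
                        header_events = header_events),
                   class = "timex_document")
  doc
}

#' Validate document invariants
#'
#' Checks tid syntax and uniqueness, span ordering and non-overlap, surface /
#' span agreement, parseability of non-empty values, and that every
#' `anchor_tid` names an earlier mention of the same document.
#'
#' @param doc a `timex_document`.
#' @return `doc`, invisibly; invariant violations raise errors.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "timex_document"))
  txs <- doc$timexes
  if (length(txs) == 0) return(invisible(doc))
  tids <- vapply(txs, `[[`, character(1), "tid")
  if (anyDuplicated(tids)) stop("validate_document: duplicate tid")
  begins <- vapply(txs, `[[`, integer(1), "begin")
  ends <- vapply(txs, `[[`, integer(1), "end")
  if (is.unsorted(begins, strictly = TRUE)) {
    stop("validate_document: timexes not ordered by span begin")
  }
  if (any(begins[-1] < ends[-length(ends)])) {
    stop("validate_document: overlapping spans")
  }
  for (i in seq_along(txs)) {
    tx <- txs[[i]]
    got <- slice(doc$text, tx$begin, tx$end)
    if (!identical(got, tx$surface)) {
      stop(sprintf("validate_document: %s surface '%s' != text slice '%s'",
                   tx$tid, tx$surface, got))
    }
    if (nzchar(tx$value)) parse_iso(tx$value)
    if (!is.na(tx$anchor_tid)) {
      j <- match(tx$anchor_tid, tids)
      if (is.na(j)) {
        stop(sprintf("validate_document: %s anchors unknown tid %s",
                     tx$tid, tx$anchor_tid))
      }
      if (j >= i) {
        stop(sprintf("validate_document: %s anchors non-earlier tid %s",
                     tx$tid, tx$anchor_tid))
      }
    }
  }
  invisible(doc)
}

# Pull structured header event dates (入院日期:YYYY-MM-DD lines) out of text.
scan_header_events <- function(text) {
  out <- list()
  paras <- split_paragraphs(text)
  for (i in seq_len(nrow(paras))) {
    line <- paras$text[i]
    for (phrase in names(HEADER_LINE_EVENTS)) {
      pat <- paste0("^", phrase, "[:：]\\s*([0-9]{4}-[0-9]{1,2}-[0-9]{1,2})")
      m <- regmatches(line, regexec(pat, line))[[1]]
      if (length(m) == 3) {
        kind <- HEADER_LINE_EVENTS[[phrase]]
        out[[kind]] <- tryCatch(parse_iso(m[2]), error = function(e) NULL)
      }
    }
  }
  out[!vapply(out, is.null, logical(1))]
}

timeml_parse_error <- function(msg, offset) {
  stop(sprintf("read_timeml: %s (at character offset %d)", msg, offset),
       call. = FALSE)
}

#' Read an inline-TimeML annotated string
#'
#' Scans for `<TIMEX3 ...>...</TIMEX3>` annotations (the only TimeML tag
#' handled), strips the markup and returns a document whose spans index into
#' the stripped text. Attributes `tid`, `Type` and `Value` are required,
#' `anchorTimeID` optional.
#'
#' @param text annotated (or plain) UTF-8 string.
#' @param doc_id document identifier.
#' @return a validated `timex_document`.
#' @export
read_timeml <- function(text, doc_id = "doc") {
  open_re <- "<TIMEX3\\b[^>]*>"
  close_tag <- "</TIMEX3>"
  opens <- gregexpr(open_re, text, perl = TRUE)[[1]]
  closes <- gregexpr(close_tag, text, fixed = TRUE)[[1]]
  n_open <- if (opens[1] == -1) 0L else length(opens)
  n_close <- if (closes[1] == -1) 0L else length(closes)
  if (n_open != n_close) {
    off <- if (n_open > 0) opens[min(n_open, n_close + 1L)] else closes[1]
    timeml_parse_error("unclosed or unmatched <TIMEX3> tag", off)
  }
  full <- gregexpr(paste0(open_re, "(.*?)", close_tag), text, perl = TRUE)[[1]]
  n_full <- if (full[1] == -1) 0L else length(full)
  if (n_full != n_open) timeml_parse_error("unclosed <TIMEX3> tag", opens[1])

  stripped <- character(0)
  timexes <- list()
  tids <- character(0)
  pos <- 1L          # 1-based cursor into annotated text
  out_len <- 0L      # chars emitted into stripped text
  if (n_full > 0) {
    starts <- as.integer(full)
    lens <- attr(full, "match.length")
    for (i in seq_len(n_full)) {
      pre <- substr(text, pos, starts[i] - 1L)
      stripped <- c(stripped, pre)
      out_len <- out_len + nchar(pre)
      frag <- substr(text, starts[i], starts[i] + lens[i] - 1L)
      open_m <- regexpr(open_re, frag, perl = TRUE)
      open_len <- attr(open_m, "match.length")
      open_tag <- substr(frag, 1L, open_len)
      surface <- substr(frag, open_len + 1L, nchar(frag) - nchar(close_tag))
      attrs <- parse_timex_attrs(open_tag, starts[i])
      if (attrs$tid %in% tids) {
        timeml_parse_error(sprintf("duplicate tid '%s'", attrs$tid), starts[i])
      }
      if (!attrs$type %in% TIMEX_TYPES) {
        timeml_parse_error(sprintf("unknown Type '%s'", attrs$type), starts[i])
      }
      tids <- c(tids, attrs$tid)
      timexes[[length(timexes) + 1L]] <- timex3(
        tid = attrs$tid, ttype = attrs$type, value = attrs$value,
        begin = out_len, end = out_len + nchar(surface), surface = surface,
        anchor_tid = attrs$anchor)
      out_len <- out_len + nchar(surface)
      stripped <- c(stripped, surface)
      pos <- starts[i] + lens[i]
    }
  }
  stripped <- paste0(paste0(stripped, collapse = ""), substr(text, pos, nchar(text)))
  validate_document(timex_document(stripped, timexes, doc_id = doc_id))
}

parse_timex_attrs <- function(open_tag, offset) {
  grab <- function(name) {
    m <- regmatches(open_tag,
                    regexec(paste0(name, '="([^"]*)"'), open_tag))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  tid <- grab("tid"); type <- grab("Type"); value <- grab("Value")
  if (is.na(tid) || is.na(type) || is.na(value)) {
    timeml_parse_error("missing required attribute (tid/Type/Value)", offset)
  }
  list(tid = tid, type = type, value = value, anchor = grab("anchorTimeID"))
}

#' Write a document as inline TimeML
#'
#' Emits `<TIMEX3 tid Type Value anchorTimeID>surface</TIMEX3>` annotations at
#' each mention's span; `read_timeml(write_timeml(doc))` reproduces `doc`.
#'
#' @param doc a `timex_document`.
#' @return annotated character scalar.
#' @export
write_timeml <- function(doc) {
  stopifnot(inherits(doc, "timex_document"))
  out <- character(0)
  pos <- 0L
  for (tx in doc$timexes) {
    out <- c(out, slice(doc$text, pos, tx$begin))
    anchor <- if (!is.na(tx$anchor_tid)) {
      sprintf(' anchorTimeID="%s"', tx$anchor_tid)
    } else ""
    out <- c(out, sprintf('<TIMEX3 tid="%s" Type="%s" Value="%s"%s>%s</TIMEX3>',
                          tx$tid, tx$ttype, tx$value, anchor, tx$surface))
    pos <- tx$end
  }
  paste0(paste0(out, collapse = ""), slice(doc$text, pos, nchar(doc$text)))
}

#' @export
print.timex_document <- function(x, ...) {
  cat(sprintf("<timex_document %s> %d chars, %d timexes\n",
              x$doc_id, nchar(x$text), length(x$timexes)))
  for (tx in x$timexes) {
    cat(sprintf("  %s %-8s %-22s %s%s\n", tx$tid, tx$ttype, tx$value, tx$surface,
                if (!is.na(tx$anchor_tid)) paste0(" -> ", tx$anchor_tid) else ""))
  }
  invisible(x)
}

# Convenience accessor: timexes as a data.frame.
#' Tabulate a document's mentions
#' @param doc a `timex_document`.
#' @return data.frame with one row per TIMEX3 mention.
#' @export
timex_table <- function(doc) {
  if (length(doc$timexes) == 0) {
    return(data.frame(tid = character(0), ttype = character(0),
                      value = character(0), anchor_tid = character(0),
                      begin = integer(0), end = integer(0),
                      surface = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(doc$timexes, function(tx) {
    data.frame(tid = tx$tid, ttype = tx$ttype, value = tx$value,
               anchor_tid = tx$anchor_tid, begin = tx$begin, end = tx$end,
               surface = tx$surface, stringsAsFactors = FALSE)
  }))
}
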