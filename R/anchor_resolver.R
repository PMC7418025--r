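# Reference-time (anchor) resolution.
#
# A mention that is not a direct time (absolute date/time) and not a DURATION
# needs a reference time. Three strategies, tried in priority order:
#   1. CRITICAL_EVENT  - a clinical milestone mention (入院 出院 手术 化疗 返院)
#                        in the same sentence whose occurrence time is known;
#   2. SECTION_PHRASE  - the enclosing paragraph opens with a section phrase
#                        (出院医嘱: ...) conventionally anchored to an event;
#   3. NEAREST_DIRECT  - the nearest direct mention, preceding preferred.
# Event occurrence times come from a direct mention in the same sentence as an
# event mention, falling back to structured header dates (入院日期/出院日期).

#' Load the anchor lexicons
#'
#' Critical-event surface forms and section phrases, shipped as an editable
#' JSON data file.
#'
#' @param path optional path to a lexicon JSON file.
#' @return list with `critical_events` and `section_phrases` (named character
#'   vectors surface form -> event kind).
#' @export
load_lexicons <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "anchor_lexicons.json", package = "zhtimex")
  }
  lex <- jsonlite::fromJSON(path)
  lex$critical_events <- unlist(lex$critical_events)
  lex$section_phrases <- unlist(lex$section_phrases)
  stopifnot(all(lex$critical_events %in% EVENT_KINDS),
            all(lex$section_phrases %in% EVENT_KINDS))
  lex
}

DIRECT_RES <- c(
  "^[0-9]{4}年(?:[0-9]{1,2}月(?:[0-9]{1,2}日)?)?$",
  "^[0-9]{4}-[0-9]{1,2}(?:-[0-9]{1,2})?$",
  "^[0-9]{4}/[0-9]{1,2}/[0-9]{1,2}$",
  "^[0-9]{4}$",
  "^[0-9]{4}[/-][0-9]{1,2}[/-][0-9]{1,2}[ T][0-9]{1,2}:[0-9]{2}(?::[0-9]{2})?$",
  "^[0-9]{4}年[0-9]{1,2}月[0-9]{1,2}日\\s*(?:上午|下午|凌晨|晚)?\\s*[0-9]{1,2}[点时](?:[0-9]{1,2}分(?:[0-9]{1,2}秒)?)?$"
)

#' Is a mention a direct time?
#'
#' Direct times are normalizable without any reference time: the type is not
#' DURATION and the surface is a complete absolute date or datetime.
#'
#' @param surface mention surface.
#' @param ttype mention type.
#' @return logical scalar.
#' @export
is_direct <- function(surface, ttype) {
  if (ttype == "DURATION") return(FALSE)
  any(vapply(DIRECT_RES, function(re) grepl(re, surface, perl = TRUE),
             logical(1)))
}

unresolved_anchor <- function(tid) {
  structure(class = c("unresolved_anchor", "error", "condition"),
            list(message = sprintf("no reference time resolvable for %s", tid),
                 call = NULL, tid = tid))
}

#' Precompute the per-document resolution context
#'
#' Sentence and paragraph segmentation, per-sentence critical-event mentions,
#' per-paragraph section phrases, and the event occurrence-time table —
#' everything [resolve_anchor()] needs that does not depend on the mention
#' being resolved.
#'
#' @param doc a `timex_document`.
#' @param lexicons anchor lexicons.
#' @param direct_values tid -> `iso_value` map of normalized direct mentions.
#' @return a context list consumed by [resolve_anchor()].
#' @export
doc_context <- function(doc, lexicons = load_lexicons(),
                        direct_values = direct_value_map(doc)) {
  sents <- split_sentences(doc$text)
  paras <- split_paragraphs(doc$text)
  tab <- timex_table(doc)
  sentence_events <- lapply(sents$text, event_mentions, lexicons = lexicons)
  paragraph_sections <- lapply(paras$text, section_phrase_prefix,
                               lexicons = lexicons)
  list(sentences = sents, paragraphs = paras, timex_tab = tab,
       sentence_events = sentence_events,
       paragraph_sections = paragraph_sections,
       event_times = event_times(doc, lexicons, direct_values,
                                 sents = sents, tab = tab,
                                 sentence_events = sentence_events))
}

# Occurrence-time table of critical events in a document: for every event
# mention that shares a sentence with a direct mention, record kind -> (value,
# tid of the direct mention). Structured header dates fill remaining kinds.
event_times <- function(doc, lexicons, direct_values,
                        sents = split_sentences(doc$text),
                        tab = timex_table(doc),
                        sentence_events = lapply(sents$text, event_mentions,
                                                 lexicons = lexicons)) {
  out <- list()
  for (s in seq_len(nrow(sents))) {
    mentions <- sentence_events[[s]]
    if (nrow(mentions) == 0) next
    in_sent <- which(tab$begin >= sents$begin[s] & tab$end <= sents$end[s])
    in_sent <- in_sent[vapply(in_sent, function(i) {
      !is.null(direct_values[[tab$tid[i]]])
    }, logical(1))]
    if (length(in_sent) == 0) next
    for (kind in unique(mentions$kind)) {
      if (!is.null(out[[kind]])) next   # first mention wins (document order)
      i <- in_sent[1]
      out[[kind]] <- list(value = direct_values[[tab$tid[i]]], tid = tab$tid[i])
    }
  }
  for (kind in names(doc$header_events)) {
    if (is.null(out[[kind]])) {
      out[[kind]] <- list(value = doc$header_events[[kind]], tid = NA_character_)
    }
  }
  out
}

# Critical-event mentions inside a sentence: data.frame(begin, end, kind),
# sentence-local 0-based offsets. A leading section phrase (出院医嘱: ...) is
# a discourse marker, not an event mention, and is skipped.
event_mentions <- function(sentence, lexicons, skip_section_prefix = TRUE) {
  skip_to <- 0L
  if (skip_section_prefix) {
    sec <- section_phrase_prefix(sentence, lexicons)
    if (!is.null(sec)) skip_to <- sec$end
  }
  out <- list()
  covered_b <- integer(0); covered_e <- integer(0)
  forms <- names(lexicons$critical_events)
  forms <- forms[order(-nchar(forms))]   # 术后 shadows 术
  for (form in forms) {
    m <- gregexpr(form, sentence, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    b <- as.integer(m) - 1L
    e <- b + nchar(form)
    keep <- b >= skip_to &
      !vapply(seq_along(b), function(i) any(b[i] < covered_e & e[i] > covered_b),
              logical(1))
    b <- b[keep]; e <- e[keep]
    if (length(b) == 0) next
    covered_b <- c(covered_b, b); covered_e <- c(covered_e, e)
    out[[length(out) + 1L]] <- data.frame(
      begin = b, end = e, kind = unname(lexicons$critical_events[form]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(begin = integer(0), end = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Section phrase opening a paragraph/sentence, followed by a colon.
section_phrase_prefix <- function(text, lexicons) {
  for (phrase in names(lexicons$section_phrases)) {
    if (grepl(paste0("^", phrase, "[:：]"), text)) {
      return(list(phrase = phrase, kind = unname(lexicons$section_phrases[phrase]),
                  end = nchar(phrase) + 1L))
    }
  }
  NULL
}

#' Resolve the reference time of a mention
#'
#' @param doc a `timex_document` whose direct mentions carry values (their
#'   `value` fields parse), or with `direct_values` supplied.
#' @param tx the `timex3` to resolve (type already predicted).
#' @param lexicons anchor lexicons from [load_lexicons()].
#' @param direct_values optional named list tid -> `iso_value` of already
#'   normalized direct mentions; computed from the document when `NULL`.
#' @param ctx optional precomputed [doc_context()] (avoids re-deriving the
#'   sentence/paragraph segmentation and event-time table per mention).
#' @return an `anchor_decision`: list(needs_anchor, anchor_tid, anchor_value,
#'   strategy) with strategy one of CRITICAL_EVENT, SECTION_PHRASE,
#'   NEAREST_DIRECT, NONE. Raises an `unresolved_anchor` condition when an
#'   anchor is needed but none is found.
#' @export
resolve_anchor <- function(doc, tx, lexicons = load_lexicons(),
                           direct_values = NULL, ctx = NULL) {
  if (is.null(direct_values)) direct_values <- direct_value_map(doc)
  if (is.null(ctx)) ctx <- doc_context(doc, lexicons, direct_values)
  decision <- function(strategy, tid = NA_character_, value = NULL) {
    structure(list(needs_anchor = strategy != "NONE", anchor_tid = tid,
                   anchor_value = value, strategy = strategy),
              class = "anchor_decision")
  }
  if (tx$ttype == "DURATION" || is_direct(tx$surface, tx$ttype)) {
    return(decision("NONE"))
  }
  ev <- ctx$event_times

  # 1. critical event in the same sentence, nearest mention with a known time
  sents <- ctx$sentences
  s <- which(sents$begin <= tx$begin & tx$end <= sents$end)
  if (length(s) == 1) {
    mentions <- ctx$sentence_events[[s]]
    if (nrow(mentions) > 0) {
      mb <- mentions$begin + sents$begin[s]
      me <- mentions$end + sents$begin[s]
      gap <- pmax(0L, pmax(mb - tx$end, tx$begin - me))
      mentions <- mentions[order(gap), , drop = FALSE]
      for (i in seq_len(nrow(mentions))) {
        known <- ev[[mentions$kind[i]]]
        if (!is.null(known)) {
          return(decision("CRITICAL_EVENT", known$tid, known$value))
        }
      }
    }
  }

  # 2. section phrase of the enclosing paragraph
  paras <- ctx$paragraphs
  p <- which(paras$begin <= tx$begin & tx$end <= paras$end)
  if (length(p) == 1) {
    sec <- ctx$paragraph_sections[[p]]
    if (!is.null(sec)) {
      known <- ev[[sec$kind]]
      if (!is.null(known)) {
        return(decision("SECTION_PHRASE", known$tid, known$value))
      }
    }
  }

  # 3. nearest direct mention: nearest preceding by span-start distance,
  #    else nearest following
  tab <- ctx$timex_tab
  cand <- which(vapply(tab$tid, function(t) !is.null(direct_values[[t]]),
                       logical(1)) & tab$tid != tx$tid)
  if (length(cand) > 0) {
    dist <- abs(tab$begin[cand] - tx$begin)
    preceding <- tab$begin[cand] < tx$begin
    ord <- order(!preceding, dist)   # preceding first, then by distance
    i <- cand[ord[1]]
    return(decision("NEAREST_DIRECT", tab$tid[i], direct_values[[tab$tid[i]]]))
  }
  stop(unresolved_anchor(tx$tid))
}

# tid -> iso_value for every direct mention whose value parses.
direct_value_map <- function(doc) {
  out <- list()
  for (tx in doc$timexes) {
    if (nzchar(tx$value) && is_direct(tx$surface, tx$ttype)) {
      out[[tx$tid]] <- tryCatch(parse_iso(tx$value), error = function(e) NULL)
    }
  }
  out[!vapply(out, is.null, logical(1))]
}
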