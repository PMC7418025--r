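# The four temporal feature groups of a mention: part-of-speech bag, trigger
# terms, trigger positions, and the TIME indicator. Encoded sparsely as named
# vectors; deterministic functions of the surface given a fixed tagger.

#' Load the trigger-term lexicon
#'
#' Temporal units and function characters (年 月 日 周 小时 点 分 秒 次 每 前
#' 后 第 ...) whose presence and position are classification features.
#'
#' @param path optional path to a JSON array of trigger terms.
#' @return character vector, longest terms first (so 小时 matches before 时).
#' @export
load_triggers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "triggers.json", package = "zhtimex")
  }
  triggers <- jsonlite::fromJSON(path)
  triggers[order(-nchar(triggers), triggers)]
}

#' Detect trigger terms in a surface string
#'
#' Longer lexicon terms shadow the shorter terms they contain at the same
#' offset (小时 suppresses 时). Positions are first-occurrence 0-based
#' character offsets within the surface.
#'
#' @param surface non-empty mention surface.
#' @param triggers trigger lexicon from [load_triggers()].
#' @return list with `trigger_ids` (character vector) and `trigger_positions`
#'   (named integer vector of first offsets).
#' @export
detect_triggers <- function(surface, triggers = load_triggers()) {
  n <- nchar(surface)
  covered <- rep(FALSE, n)   # character claimed by a longer trigger
  ids <- character(0)
  pos <- integer(0)
  for (trg in triggers) {    # longest first
    m <- gregexpr(trg, surface, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    len <- nchar(trg)
    free <- starts[!vapply(starts, function(s) any(covered[s:(s + len - 1)]),
                           logical(1))]
    if (length(free) == 0) next
    for (s in free) covered[s:(s + len - 1)] <- TRUE
    ids <- c(ids, trg)
    pos <- c(pos, stats::setNames(min(free) - 1L, trg))
  }
  ord <- order(pos)
  list(trigger_ids = ids[ord], trigger_positions = pos[ord])
}

#' TIME-type indicator
#'
#' TRUE iff the surface shows clock features: colon-separated digit pairs,
#' 点/时 followed by digits, or a day-part word (上午 下午 凌晨 晚).
#'
#' @param surface non-empty mention surface.
#' @return logical scalar.
#' @export
time_indicator <- function(surface) {
  grepl("[0-9]{1,2}:[0-9]{2}", surface) ||
    grepl("[点时][0-9]", surface) ||
    grepl("上午|下午|凌晨|晚", surface)
}

#' The default lexicon-based part-of-speech tagger
#'
#' A replaceable tagger port: any function mapping a string to a
#' data.frame(token, tag) whose concatenated tokens reconstruct the input can
#' stand in (e.g. an adapter to an external Chinese tagger). The shipped
#' tagger assigns date/number/temporal-unit tags from fixed character classes:
#' CDY four-digit (year-like) numbers, CD other Arabic numbers, CN Chinese
#' numerals, NT temporal nouns/units, M measure word 个, OD ordinal prefix 第,
#' DT 每, LC localizers 前/后/上/下, AD approximation 余约多, PU punctuation
#' and space, NN everything else.
#'
#' @return a tagger function.
#' @export
default_tagger <- function() {
  lex_re <- c(
    CDY = "[0-9]{4}",
    CD  = "[0-9]+",
    CN  = "[一二三四五六七八九十两零]+",
    NT  = "星期|小时|分钟|上午|下午|凌晨|[年月日号周天时点分秒晚晨]",
    M   = "个",
    OD  = "第",
    DT  = "每",
    LC  = "[前后内上下]",
    AD  = "[余约多]",
    PU  = "[[:space:]、，,。:：;；/-]"
  )
  big <- paste0("(", paste0("?<", names(lex_re), ">", lex_re, collapse = ")|("),
                ")")
  function(text) {
    toks <- character(0); tags <- character(0)
    pos <- 1L
    n <- nchar(text)
    while (pos <= n) {
      rest <- substr(text, pos, n)
      m <- regexpr(paste0("^(?:", big, ")"), rest, perl = TRUE)
      if (m == 1) {
        cs <- attr(m, "capture.start")[1, ]
        cl <- attr(m, "capture.length")[1, ]
        hit <- which(cs > 0 & cl > 0)[1]
        tok <- substr(rest, cs[hit], cs[hit] + cl[hit] - 1L)
        toks <- c(toks, tok); tags <- c(tags, names(lex_re)[hit])
        pos <- pos + nchar(tok)
      } else {
        toks <- c(toks, substr(rest, 1L, 1L)); tags <- c(tags, "NN")
        pos <- pos + 1L
      }
    }
    data.frame(token = toks, tag = tags, stringsAsFactors = FALSE)
  }
}

#' Build the feature vector of one mention
#'
#' Merges the four feature groups computed over the mention surface into one
#' record. Deterministic given the tagger; mentions with identical surfaces
#' get identical vectors.
#'
#' @param surface mention surface string.
#' @param tagger a tagger port (see [default_tagger()]).
#' @param triggers trigger lexicon.
#' @param label optional gold type label (training only).
#' @return a `feature_vector` list with fields `pos_bag`, `trigger_ids`,
#'   `trigger_positions`, `time_indicator`, `label`, `surface`.
#' @export
build_vector <- function(surface, tagger = default_tagger(),
                         triggers = load_triggers(), label = NA_character_) {
  if (!nzchar(surface)) stop("build_vector: empty surface")
  tagged <- tagger(surface)
  if (!identical(gsub("[[:space:]]", "", paste0(tagged$token, collapse = "")),
                 gsub("[[:space:]]", "", surface))) {
    stop(sprintf("build_vector: tagger does not reconstruct surface '%s'", surface))
  }
  pos_bag <- table(tagged$tag)
  trg <- detect_triggers(surface, triggers)
  structure(list(
    pos_bag = stats::setNames(as.integer(pos_bag), names(pos_bag)),
    trigger_ids = trg$trigger_ids,
    trigger_positions = trg$trigger_positions,
    time_indicator = time_indicator(surface),
    label = label,
    surface = surface
  ), class = "feature_vector")
}

#' Feature vectors for every mention of a document set
#'
#' @param docs list of `timex_document`s with (gold or predicted) types.
#' @param tagger,triggers see [build_vector()].
#' @param labelled use each mention's type as the training label.
#' @return list of `feature_vector`s.
#' @export
corpus_vectors <- function(docs, tagger = default_tagger(),
                           triggers = load_triggers(), labelled = TRUE) {
  cache <- new.env(parent = emptyenv())
  out <- list()
  for (doc in docs) {
    for (tx in doc$timexes) {
      key <- paste0(tx$surface, "\r", if (labelled) tx$ttype else "")
      v <- cache[[key]]
      if (is.null(v)) {
        v <- build_vector(tx$surface, tagger, triggers,
                          label = if (labelled) tx$ttype else NA_character_)
        cache[[key]] <- v
      }
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

# Serialize feature vectors as JSON-lines (one record per mention).
#' Write feature vectors to a JSON-lines file
#' @param vectors list of `feature_vector`s.
#' @param path output path.
#' @export
write_features <- function(vectors, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (v in vectors) {
    rec <- list(surface = v$surface, pos_bag = as.list(v$pos_bag),
                trigger_ids = v$trigger_ids,
                trigger_positions = as.list(v$trigger_positions),
                time_indicator = v$time_indicator, label = v$label)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
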