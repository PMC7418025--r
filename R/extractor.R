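# Heuristic-rule + learned-pattern span extraction.
#
# The rule inventory covers the surface families seen in Chinese discharge
# summaries: absolute dates (2014年6月3日 / 2014-06-03 / 2014/6/3 / 22/9),
# clock times (上午7点20分4秒, 7:48:16), relative offsets (6天前, 72小时后),
# durations (两年五个月, 1年余), day sets (第7、10、14天) and deictics (目前).
# Overlaps are resolved longest-match-first, ties by leftmost.

# Characters a learned extraction pattern's placeholder may match.
TE_CHARSET <- "[0-9一二三四五六七八九十两零年月日天周点分秒时第每、,，/:个余约多小星期前后上下午凌晨早晚-]"

#' Load the shipped (or a custom) extraction rule set
#'
#' Rules are shipped as an editable JSON data file so deployments can extend
#' the inventory without code changes.
#'
#' @param path path to a rules JSON file; default: the file shipped with the
#'   package.
#' @return data.frame with columns `rule_id`, `family`, `pattern`.
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "extraction_rules.json", package = "zhtimex")
  }
  rules <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  stopifnot(all(c("rule_id", "family", "pattern") %in% names(rules)))
  for (p in rules$pattern) regexpr(p, "", perl = TRUE)  # must compile
  rules
}

rule_matches <- function(text, rules) {
  out <- list()
  for (i in seq_len(nrow(rules))) {
    m <- gregexpr(rules$pattern[i], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    out[[length(out) + 1L]] <- data.frame(
      begin = as.integer(m) - 1L,
      end = as.integer(m) - 1L + attr(m, "match.length"),
      rule_id = rules$rule_id[i], family = rules$family[i],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(begin = integer(0), end = integer(0),
                      rule_id = character(0), family = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Greedy longest-match selection: repeatedly keep the longest remaining
# candidate (ties by leftmost begin), discarding overlaps.
select_spans <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-(cand$end - cand$begin), cand$begin), , drop = FALSE]
  kept <- logical(nrow(cand))
  taken_b <- integer(0); taken_e <- integer(0)
  for (i in seq_len(nrow(cand))) {
    b <- cand$begin[i]; e <- cand$end[i]
    if (!any(b < taken_e & e > taken_b)) {
      kept[i] <- TRUE
      taken_b <- c(taken_b, b); taken_e <- c(taken_e, e)
    }
  }
  out <- cand[kept, , drop = FALSE]
  out[order(out$begin), , drop = FALSE]
}

#' Extract temporal-expression spans from raw text
#'
#' Applies the heuristic rules, resolves overlaps longest-match-first (ties by
#' leftmost), then lets learned EXTRACTION context patterns add spans their
#' template matches that the rules missed. Adding patterns never removes a
#' rule-produced span.
#'
#' @param text unicode document text.
#' @param rules rule set from [load_rules()].
#' @param patterns optional pattern data.frame (see [learn_patterns()]) whose
#'   EXTRACTION rows propose additional spans.
#' @return data.frame with columns `begin`, `end` (0-based half-open),
#'   `surface`, `family`, sorted by `begin`, spans non-overlapping.
#' @export
extract_spans <- function(text, rules = load_rules(), patterns = NULL) {
  empty <- data.frame(begin = integer(0), end = integer(0),
                      surface = character(0), family = character(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  cand <- rule_matches(text, rules)
  sel <- select_spans(cand)
  if (!is.null(patterns) && nrow(patterns) > 0) {
    extra <- pattern_spans(text, patterns[patterns$purpose == "EXTRACTION", ,
                                          drop = FALSE])
    if (nrow(extra) > 0) {
      # rule spans always win overlaps
      ok <- vapply(seq_len(nrow(extra)), function(i) {
        !any(extra$begin[i] < sel$end & extra$end[i] > sel$begin)
      }, logical(1))
      extra <- extra[ok, , drop = FALSE]
      if (nrow(extra) > 0) {
        sel <- rbind(sel, extra)
        sel <- select_spans(sel)
      }
    }
  }
  if (nrow(sel) == 0) return(empty)
  data.frame(begin = sel$begin, end = sel$end,
             surface = substring(text, sel$begin + 1L, sel$end),
             family = sel$family, stringsAsFactors = FALSE)
}

# Spans proposed by EXTRACTION-purpose context patterns: the template's
# left/right context matched literally, the placeholder matched by a bounded
# run of temporal-expression characters.
pattern_spans <- function(text, patterns) {
  empty <- data.frame(begin = integer(0), end = integer(0),
                      rule_id = character(0), family = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(patterns) || nrow(patterns) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(patterns))) {
    ctx <- split_template(patterns$template[i])
    if (!nzchar(ctx$left) && !nzchar(ctx$right)) next  # bare placeholder: no signal
    re <- paste0(escape_regex(ctx$left), "(", TE_CHARSET, "{1,20}?)",
                 escape_regex(ctx$right))
    m <- gregexpr(re, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    cs <- attr(m, "capture.start")[, 1]
    cl <- attr(m, "capture.length")[, 1]
    out[[length(out) + 1L]] <- data.frame(
      begin = as.integer(cs) - 1L, end = as.integer(cs) - 1L + as.integer(cl),
      rule_id = paste0("pattern:", patterns$template[i]), family = "PATTERN",
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  unique(do.call(rbind, out))
}

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.<>])", "\\\\\\1", s)

# Split a template at its single placeholder into left/right context strings.
split_template <- function(template) {
  idx <- regexpr(PLACEHOLDER, template, fixed = TRUE)
  if (idx == -1) stop(sprintf("template '%s' lacks the %s placeholder",
                              template, PLACEHOLDER))
  list(left = substr(template, 1L, idx - 1L),
       right = substr(template, idx + nchar(PLACEHOLDER), nchar(template)))
}
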