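# Context-pattern mining: learn short character templates around annotated
# temporal expressions, scored by support (match count) and confidence
# (correct-match fraction), thresholded at 0.8 and reduced to their most
# general substring representatives.
#
# A template is a string containing the placeholder token "<TIMEX3>" exactly
# once; the placeholder counts as one character for length purposes.

#' Miner configuration
#'
#' @param max_pattern_len maximum template length in characters, the
#'   placeholder counting as one. The default 6 allows up to five context
#'   characters around a mention.
#' @param threshold confidence threshold in `[0,1]`; a pattern is kept when its
#'   confidence is greater than or equal to it.
#' @return a `miner_config` list.
#' @export
miner_config <- function(max_pattern_len = 6L, threshold = 0.8) {
  stopifnot(max_pattern_len >= 1, threshold >= 0, threshold <= 1)
  structure(list(max_pattern_len = as.integer(max_pattern_len),
                 threshold = threshold),
            class = "miner_config")
}

#' Replace TIMEX3 annotations with the placeholder token
#'
#' Each inline annotation (tag plus annotated surface) is substituted by the
#' single placeholder token `<TIMEX3>`; all other characters are preserved.
#'
#' @param annotated_sentence a string containing at least one
#'   `<TIMEX3 ...>...</TIMEX3>` annotation.
#' @return the templated string.
#' @export
substitute_tags <- function(annotated_sentence) {
  re <- "<TIMEX3\\b[^>]*>.*?</TIMEX3>"
  if (!grepl(re, annotated_sentence, perl = TRUE)) {
    stop("substitute_tags: sentence contains no TIMEX3 annotation")
  }
  gsub(re, PLACEHOLDER, annotated_sentence, perl = TRUE)
}

# Tokenize a templated string: each placeholder is one token, every other
# character is its own token.
template_tokens <- function(templated) {
  parts <- strsplit(templated, PLACEHOLDER, fixed = TRUE)[[1]]
  n_ph <- (nchar(templated) -
           nchar(gsub(PLACEHOLDER, "", templated, fixed = TRUE))) /
          nchar(PLACEHOLDER)
  if (length(parts) == 0) parts <- ""
  toks <- character(0)
  for (i in seq_along(parts)) {
    if (nzchar(parts[i])) toks <- c(toks, strsplit(parts[i], "", fixed = TRUE)[[1]])
    if (i <= n_ph) toks <- c(toks, PLACEHOLDER)
  }
  # trailing placeholders beyond split parts
  while (sum(toks == PLACEHOLDER) < n_ph) toks <- c(toks, PLACEHOLDER)
  toks
}

#' Enumerate candidate templates around each placeholder
#'
#' All contiguous substrings of the templated string that contain exactly one
#' placeholder and have length at most `max_pattern_len` (placeholder = one
#' character), including the bare placeholder. Duplicates are removed;
#' ordering is deterministic (by left extent, then right extent, per
#' placeholder occurrence).
#'
#' @param templated output of [substitute_tags()].
#' @param cfg a [miner_config()].
#' @return character vector of candidate templates.
#' @export
enumerate_candidates <- function(templated, cfg = miner_config()) {
  toks <- template_tokens(templated)
  ph_idx <- which(toks == PLACEHOLDER)
  if (length(ph_idx) == 0) {
    stop("enumerate_candidates: templated string contains no placeholder")
  }
  out <- character(0)
  for (p in ph_idx) {
    # extents may not cross another placeholder (exactly one per template)
    prev_ph <- max(c(0L, ph_idx[ph_idx < p]))
    next_ph <- min(c(length(toks) + 1L, ph_idx[ph_idx > p]))
    max_l <- min(p - prev_ph - 1L, cfg$max_pattern_len - 1L)
    for (l in 0:max_l) {
      max_r <- min(next_ph - p - 1L, cfg$max_pattern_len - 1L - l)
      for (r in 0:max_r) {
        out <- c(out, paste0(toks[(p - l):(p + r)], collapse = ""))
      }
    }
  }
  unique(out)
}

# Per-document site table used by the scorer: one row per site with its left
# and right context strings and a correctness flag for the given purpose.
site_table <- function(doc, purpose, rules, ctx_len) {
  tab <- timex_table(doc)
  gold_key <- paste(tab$begin, tab$end)
  values <- stats::setNames(tab$value, tab$tid)
  if (purpose == "NORM_ANCHOR_EQUALS") {
    sites <- tab[, c("begin", "end"), drop = FALSE]
    anchor_val <- ifelse(is.na(tab$anchor_tid), NA_character_,
                         unname(values[tab$anchor_tid]))
    correct <- !is.na(anchor_val) & nzchar(tab$value) & tab$value == anchor_val
  } else {
    ext <- extract_spans(doc$text, rules)
    sites <- unique(rbind(ext[, c("begin", "end")], tab[, c("begin", "end")]))
    correct <- paste(sites$begin, sites$end) %in% gold_key
  }
  if (nrow(sites) == 0) {
    return(data.frame(left = character(0), right = character(0),
                      correct = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(
    left = substring(doc$text, pmax(1L, sites$begin - ctx_len + 1L), sites$begin),
    right = substring(doc$text, sites$end + 1L, sites$end + ctx_len),
    correct = correct, stringsAsFactors = FALSE)
}

#' Score candidate templates against an annotated corpus
#'
#' For each candidate, `support` counts the corpus sites whose context matches
#' the template; `confidence` is the fraction of those sites that are correct.
#' For purpose `NORM_ANCHOR_EQUALS`, sites are the gold mentions and a site is
#' correct when the mention's gold Value equals the gold Value of its anchor.
#' For purpose `EXTRACTION`, sites are the union of rule-extracted candidate
#' spans and gold spans, and a site is correct when it coincides with a gold
#' span.
#'
#' @param candidates character vector of templates.
#' @param corpus list of gold-annotated `timex_document`s.
#' @param purpose `"NORM_ANCHOR_EQUALS"` or `"EXTRACTION"`.
#' @param rules rule set used to propose EXTRACTION sites.
#' @return data.frame with columns `template`, `purpose`, `support`,
#'   `confidence` (NA when support is 0).
#' @export
score_patterns <- function(candidates, corpus,
                           purpose = c("NORM_ANCHOR_EQUALS", "EXTRACTION"),
                           rules = load_rules()) {
  purpose <- match.arg(purpose)
  if (length(candidates) == 0) {
    return(data.frame(template = character(0), purpose = character(0),
                      support = integer(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (length(corpus) == 0) stop("score_patterns: corpus must be non-empty")
  ctx_len <- max(nchar(gsub(PLACEHOLDER, "", candidates, fixed = TRUE))) + 1L
  sites <- do.call(rbind, lapply(corpus, site_table, purpose = purpose,
                                 rules = rules, ctx_len = ctx_len))
  support <- integer(length(candidates))
  confidence <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    ctx <- split_template(candidates[i])
    hit <- rep(TRUE, nrow(sites))
    if (nzchar(ctx$left)) hit <- hit & endsWith(sites$left, ctx$left)
    if (nzchar(ctx$right)) hit <- hit & startsWith(sites$right, ctx$right)
    support[i] <- sum(hit)
    if (support[i] > 0) confidence[i] <- sum(sites$correct[hit]) / support[i]
  }
  data.frame(template = candidates, purpose = purpose, support = support,
             confidence = confidence, stringsAsFactors = FALSE)
}

#' Threshold and substring-reduce scored patterns
#'
#' Keeps patterns whose confidence is greater than or equal to the threshold
#' (and support at least 1), then removes any pattern for which a kept strict
#' substring pattern has confidence at least as high — the shorter, more
#' general template survives unless the longer one is strictly more confident.
#'
#' @param patterns scored pattern data.frame from [score_patterns()].
#' @param cfg a [miner_config()].
#' @return filtered data.frame sorted by confidence, support (both
#'   decreasing), then template.
#' @export
filter_patterns <- function(patterns, cfg = miner_config()) {
  keep <- !is.na(patterns$confidence) & patterns$support >= 1 &
    patterns$confidence >= cfg$threshold
  pats <- patterns[keep, , drop = FALSE]
  if (nrow(pats) > 1) {
    drop <- logical(nrow(pats))
    for (i in seq_len(nrow(pats))) {
      for (j in seq_len(nrow(pats))) {
        if (i == j) next
        ti <- pats$template[i]; tj <- pats$template[j]
        if (nchar(tj) < nchar(ti) && grepl(tj, ti, fixed = TRUE) &&
            pats$confidence[j] >= pats$confidence[i]) {
          drop[i] <- TRUE
          break
        }
      }
    }
    pats <- pats[!drop, , drop = FALSE]
  }
  pats <- pats[order(-pats$confidence, -pats$support, pats$template), ,
               drop = FALSE]
  rownames(pats) <- NULL
  pats
}

#' Learn context patterns from an annotated corpus
#'
#' The full mining pipeline: sentence splitting (on 。！？；and newline),
#' placeholder substitution of the target mentions, candidate enumeration,
#' corpus-wide scoring, and threshold + substring filtering. For purpose
#' `NORM_ANCHOR_EQUALS` the target mentions are those whose gold Value equals
#' their anchor's gold Value; for `EXTRACTION`, all gold mentions.
#'
#' @param corpus list of gold-annotated `timex_document`s.
#' @param cfg a [miner_config()].
#' @param purpose which pattern group to learn.
#' @param rules rule set (used for EXTRACTION scoring sites).
#' @return filtered pattern data.frame (possibly empty).
#' @export
learn_patterns <- function(corpus, cfg = miner_config(),
                           purpose = c("NORM_ANCHOR_EQUALS", "EXTRACTION"),
                           rules = load_rules()) {
  purpose <- match.arg(purpose)
  empty <- data.frame(template = character(0), purpose = character(0),
                      support = integer(0), confidence = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(corpus) == 0) return(empty)
  candidates <- character(0)
  for (doc in corpus) {
    tab <- timex_table(doc)
    if (nrow(tab) == 0) next
    if (purpose == "NORM_ANCHOR_EQUALS") {
      values <- stats::setNames(tab$value, tab$tid)
      anchor_val <- ifelse(is.na(tab$anchor_tid), NA_character_,
                           unname(values[tab$anchor_tid]))
      target <- !is.na(anchor_val) & nzchar(tab$value) & tab$value == anchor_val
    } else {
      target <- rep(TRUE, nrow(tab))
    }
    if (!any(target)) next
    sents <- split_sentences(doc$text)
    for (s in seq_len(nrow(sents))) {
      sb <- sents$begin[s]; se <- sents$end[s]
      in_sent <- which(target & tab$begin >= sb & tab$end <= se)
      if (length(in_sent) == 0) next
      templated <- template_of_sentence(sents$text[s], tab$begin[in_sent] - sb,
                                        tab$end[in_sent] - sb)
      candidates <- c(candidates, enumerate_candidates(templated, cfg))
    }
  }
  candidates <- unique(candidates)
  if (length(candidates) == 0) return(empty)
  scored <- score_patterns(candidates, corpus, purpose, rules)
  filter_patterns(scored, cfg)
}

# Replace the given (0-based, sentence-local) spans with placeholders.
template_of_sentence <- function(sentence, begins, ends) {
  ord <- order(begins)
  begins <- begins[ord]; ends <- ends[ord]
  out <- character(0); pos <- 0L
  for (i in seq_along(begins)) {
    out <- c(out, slice(sentence, pos, begins[i]), PLACEHOLDER)
    pos <- ends[i]
  }
  paste0(paste0(out, collapse = ""), slice(sentence, pos, nchar(sentence)))
}

#' Read / write pattern files
#'
#' Patterns persist as a four-column TSV: template, purpose, support,
#' confidence.
#'
#' @param patterns pattern data.frame.
#' @param path file path.
#' @return `read_patterns` returns the pattern data.frame.
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(patterns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    encoding = "UTF-8")
}
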