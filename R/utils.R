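# Shared helpers: Chinese numerals, sentence/paragraph segmentation, seeded RNG.

# Sentence delimiters used throughout the package (miner, anchor resolver).
SENTENCE_DELIMS <- c("。", "！", "？", "；", ";", "!", "?", "\n")

PLACEHOLDER <- "<TIMEX3>"

#' Convert a Chinese or Arabic numeral string to an integer
#'
#' Understands Arabic digits and Chinese numerals up to 99 (including
#' 两 for 2, as in 两年 "two years").
#'
#' @param s a numeral string, e.g. "72", "五", "二十一".
#' @return integer scalar; `NA` if `s` is not a recognizable numeral.
#' @export
zh_numeral <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NA_integer_)
  if (grepl("^[0-9]+$", s)) return(as.integer(s))
  digits <- c(
    "零" = 0L, "一" = 1L, "二" = 2L, "两" = 2L, "三" = 3L,
    "四" = 4L, "五" = 5L, "六" = 6L, "七" = 7L, "八" = 8L,
    "九" = 9L
  )
  ten <- "十"
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, c(names(digits), ten))
  if (length(bad) > 0) return(NA_integer_)
  pos_ten <- which(chars == ten)
  if (length(pos_ten) > 1) return(NA_integer_)
  if (length(pos_ten) == 0) {
    if (length(chars) != 1) return(NA_integer_)  # no positional forms like 九九
    return(unname(digits[chars]))
  }
  left <- chars[seq_len(pos_ten - 1)]
  right <- chars[seq_len(length(chars)) > pos_ten]
  tens <- if (length(left) == 0) 1L else if (length(left) == 1) unname(digits[left]) else return(NA_integer_)
  ones <- if (length(right) == 0) 0L else if (length(right) == 1) unname(digits[right]) else return(NA_integer_)
  if (is.na(tens) || is.na(ones)) return(NA_integer_)
  tens * 10L + ones
}

# Split text into sentences, keeping 0-based half-open character offsets.
# Returns data.frame(begin, end, text); delimiter characters are attached to
# the preceding sentence.
split_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0) {
    return(data.frame(begin = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_delim <- chars %in% SENTENCE_DELIMS
  ends <- which(is_delim)
  begins <- c(1L, ends + 1L)
  ends <- c(ends, n)
  keep <- begins <= ends
  begins <- begins[keep]; ends <- ends[keep]
  txt <- substring(text, begins, ends)
  nonempty <- nzchar(trimws(txt))
  data.frame(begin = begins[nonempty] - 1L, end = ends[nonempty],
             text = txt[nonempty], stringsAsFactors = FALSE)
}

# Split text into paragraphs (lines). 0-based half-open offsets.
split_paragraphs <- function(text) {
  n <- nchar(text)
  if (n == 0) {
    return(data.frame(begin = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  ends <- which(chars == "\n")
  begins <- c(1L, ends + 1L)
  ends <- c(ends, n)
  keep <- begins <= ends
  begins <- begins[keep]; ends <- ends[keep]
  txt <- sub("\n$", "", substring(text, begins, ends))
  data.frame(begin = begins - 1L, end = begins - 1L + nchar(txt), text = txt,
             stringsAsFactors = FALSE)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 0-based half-open span slicing of UTF-8 text.
slice <- function(text, begin, end) substr(text, begin + 1L, end)

`%||%` <- function(a, b) if (is.null(a)) b else a
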