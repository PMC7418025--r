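# Seeded synthetic Chinese discharge summaries with gold TIMEX3 annotations.
#
# Documents are assembled from templates so gold annotations are correct by
# construction: structured header date lines, a diagnosis section, a narrative
# with critical-event sentences carrying direct dates/times, relative and
# duration mentions, a chief-complaint sentence whose mention's value equals
# its reference time (the anchor-equality context the pattern miner should
# recover), a discharge-status section with a deictic, and discharge
# instructions with a day set and an hour offset. Gold values of anaphoric
# mentions are computed from their gold anchors with the normalizer's own
# calendar arithmetic; anchors are chosen by the generator's independent
# bookkeeping of the templates' semantics, not by running the resolver.

#' Generator configuration
#'
#' @param n_docs number of documents.
#' @param seed RNG seed; the corpus is byte-identical per seed.
#' @param mean_tes_per_doc target mean mentions per document (default 13.4,
#'   the density typical of annotated discharge summaries).
#' @param type_mix sampling probabilities over DATE/TIME/DURATION/SET for the
#'   variable extra mentions beyond the fixed document backbone.
#' @param anaphoric_fraction probability that an extra DATE mention is
#'   relative (anchor-requiring) rather than absolute.
#' @param typo_rate fraction of documents whose discharge-date header is
#'   corrupted to "出院日期:出院日期" (a real-world failure mode: the
#'   reference time for discharge-anchored mentions is then missing).
#' @param planted_pattern_rate probability that the anchor-equal
#'   chief-complaint mention is wrapped in the fixed context 术后...余 (the
#'   planted template); otherwise a variant context without 余 is used.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_docs = 10L, seed = 1L, mean_tes_per_doc = 13.4,
                       type_mix = c(DATE = 0.70, TIME = 0.10,
                                    DURATION = 0.15, SET = 0.05),
                       anaphoric_fraction = 0.35, typo_rate = 0,
                       planted_pattern_rate = 1) {
  stopifnot(n_docs >= 1, mean_tes_per_doc > 0,
            abs(sum(type_mix) - 1) < 1e-9, all(type_mix >= 0),
            typo_rate >= 0, typo_rate <= 1,
            planted_pattern_rate >= 0, planted_pattern_rate <= 1,
            anaphoric_fraction >= 0, anaphoric_fraction <= 1)
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 mean_tes_per_doc = mean_tes_per_doc, type_mix = type_mix,
                 anaphoric_fraction = anaphoric_fraction,
                 typo_rate = typo_rate,
                 planted_pattern_rate = planted_pattern_rate),
            class = "gen_config")
}

# Mentions per document contributed by the fixed backbone (without header typo).
BACKBONE_TES <- 12L

fmt_dash <- function(d) format(d, "%Y-%m-%d")
fmt_cn <- function(d) {
  lt <- as.POSIXlt(d)
  sprintf("%d年%d月%d日", lt$year + 1900L, lt$mon + 1L, lt$mday)
}
fmt_slash_dt <- function(d, h, mi, s) {
  lt <- as.POSIXlt(d)
  sprintf("%d/%d/%d %d:%02d:%02d", lt$year + 1900L, lt$mon + 1L, lt$mday,
          h, mi, s)
}

#' Generate a synthetic annotated corpus
#'
#' @param cfg a [gen_config()].
#' @return list of validated gold `timex_document`s.
#' @export
generate_corpus <- function(cfg = gen_config()) {
  with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_docs), function(i) {
      generate_doc(cfg, sprintf("synth%04d", i))
    })
  })
}

generate_doc <- function(cfg, doc_id) {
  # document builder state: text pieces + mention registry
  pieces <- character(0)
  tes <- list()          # list of (begin, end, surface, ttype, value, anchor_idx)
  pos <- 0L
  last_direct <- NA_integer_   # index of most recent direct mention
  put <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  put_te <- function(surface, ttype, value, anchor_idx = NA_integer_,
                     direct = FALSE) {
    tes[[length(tes) + 1L]] <<- list(begin = pos, end = pos + nchar(surface),
                                     surface = surface, ttype = ttype,
                                     value = value, anchor_idx = anchor_idx)
    if (direct) last_direct <<- length(tes)
    put(surface)
    length(tes)
  }
  te_value <- function(idx) parse_iso(tes[[idx]]$value)
  rel_te <- function(n, unit_chr, dir_chr) {
    # relative mention anchored to the nearest preceding direct mention
    surface <- paste0(n, unit_chr, dir_chr)
    v <- apply_offset(te_value(last_direct), parse_relative(surface))
    put_te(surface, "DATE", format_iso(v), anchor_idx = last_direct)
  }

  year_start <- as.Date(sprintf("%d-%02d-01", sample(2012:2016, 1),
                                sample(3:9, 1)))
  adm <- year_start + sample(0:27, 1)
  surg <- adm + 2L
  chemo <- adm + 6L
  dis <- adm + sample(10:20, 1)
  side <- sample(c("左", "右"), 1)
  typo <- stats::runif(1) < cfg$typo_rate

  # header
  put("入院日期:")
  adm_idx <- put_te(fmt_dash(adm), "DATE", fmt_dash(adm), direct = TRUE)
  put("\n出院日期:")
  dis_idx <- NA_integer_
  if (typo) {
    put("出院日期")
  } else {
    dis_idx <- put_te(fmt_dash(dis), "DATE", fmt_dash(dis), direct = TRUE)
  }
  put(sprintf("\n入院诊断:%s乳腺癌。\n", side))

  # narrative
  put("患者")
  rel_te(sample(2:9, 1), sample(c("天", "周"), 1), "前")
  put(sprintf("发觉%s乳房肿物。于", side))
  surg_idx <- put_te(fmt_cn(surg), "DATE", fmt_dash(surg), direct = TRUE)
  put(sprintf("行%s乳癌改良根治术。", side))
  chemo_idx <- put_te(fmt_dash(chemo), "DATE", fmt_dash(chemo), direct = TRUE)
  put("行第一次化疗。")
  tstr <- fmt_slash_dt(adm + 1L, sample(7:16, 1), sample(0:59, 1), sample(0:59, 1))
  put_te(tstr, "TIME", format_iso(normalize_direct(tstr, "TIME")), direct = TRUE)
  put("行血常规检查。术后")
  nd <- sample(2:6, 1)
  put_te(paste0(nd, "天"), "DURATION", format_iso(iso_duration(days = nd)))
  put("出现伤口疼痛。出院后")
  nw <- sample(1:4, 1)
  put_te(paste0(nw, "周"), "DURATION", format_iso(iso_duration(weeks = nw)))
  put("余门诊复查。")

  # anchor-equal chief complaint (value equals the surgery reference time)
  planted <- stats::runif(1) < cfg$planted_pattern_rate
  put(sprintf("主诉:%s乳腺癌术后", side))
  put_te(paste0(sample(2:9, 1), "月"), "DATE", fmt_dash(surg),
         anchor_idx = surg_idx)
  put(if (planted) "余,返院行化疗。" else ",返院行化疗。")

  # stochastic extras
  n_extra <- stats::rpois(1, max(0, cfg$mean_tes_per_doc - BACKBONE_TES))
  if (n_extra > 0) {
    kinds <- sample(names(cfg$type_mix), n_extra, replace = TRUE,
                    prob = cfg$type_mix)
    set_extras <- sum(kinds == "SET")
    for (kind in kinds[kinds != "SET"]) {
      if (kind == "DATE") {
        if (stats::runif(1) < cfg$anaphoric_fraction) {
          lead <- sample(c("出现胸闷。", "复查血象。", "门诊随诊。"), 1)
          rel_te(sample(2:9, 1), sample(c("天", "周"), 1),
                 sample(c("前", "后"), 1))
          put(lead)
        } else {
          d2 <- adm + sample(1:9, 1)
          s2 <- if (stats::runif(1) < 0.5) fmt_cn(d2) else fmt_dash(d2)
          put("于")
          put_te(s2, "DATE", fmt_dash(d2), direct = TRUE)
          put(sample(c("行B超检查。", "复查肝功能。", "行心电图检查。"), 1))
        }
      } else if (kind == "TIME") {
        t2 <- fmt_slash_dt(adm + sample(1:9, 1), sample(7:16, 1),
                           sample(0:59, 1), sample(0:59, 1))
        put_te(t2, "TIME", format_iso(normalize_direct(t2, "TIME")),
               direct = TRUE)
        put(sample(c("测体温。", "行心脏彩超检查。"), 1))
      } else {
        dur <- sample(list(
          list(s = "两年五个月", v = iso_duration(years = 2, months = 5)),
          list(s = "3个月", v = iso_duration(months = 3)),
          list(s = "1年余", v = iso_duration(years = 1)),
          list(s = "5天", v = iso_duration(days = 5))
        ), 1)[[1]]
        put(sample(c("咳嗽", "腹痛", "头晕"), 1))
        put_te(dur$s, "DURATION", format_iso(dur$v))
        put("。")
      }
    }
  } else {
    set_extras <- 0L
  }
  put("\n")

  # discharge status: deictic anchored to the discharge date (or, when the
  # header is corrupted, to the nearest preceding direct mention)
  put("出院情况:")
  deictic_anchor <- if (!typo) dis_idx else last_direct
  put_te("目前", "DATE", tes[[deictic_anchor]]$value,
         anchor_idx = deictic_anchor)
  put("患者一般情况可,伤口愈合良好。\n")

  # discharge instructions
  put("出院医嘱:1、化疗后")
  ks <- sort(sample(2:15, 3))
  set_surface <- paste0("第", paste(ks, collapse = "、"), "天")
  put_te(set_surface, "SET",
         format_iso(normalize_set(set_surface, te_value(chemo_idx))),
         anchor_idx = chemo_idx)
  put("复查血象;2、")
  h <- sample(c(24L, 48L, 72L), 1)
  hour_anchor <- if (!typo) dis_idx else last_direct
  hour_surface <- paste0(h, "小时后")
  put_te(hour_surface, "DATE",
         format_iso(apply_offset(te_value(hour_anchor),
                                 parse_relative(hour_surface))),
         anchor_idx = hour_anchor)
  put("自行拆除绷带;")
  item <- 3L
  if (set_extras > 0) {
    for (j in seq_len(set_extras)) {
      ks2 <- sort(sample(2:15, 2))
      s2 <- paste0("第", paste(ks2, collapse = "、"), "天")
      put(sprintf("%d、化疗后", item))
      put_te(s2, "SET", format_iso(normalize_set(s2, te_value(chemo_idx))),
             anchor_idx = chemo_idx)
      put("复查肝功能;")
      item <- item + 1L
    }
  }
  put(sprintf("%d、不适随诊。\n", item))

  text <- paste0(pieces, collapse = "")
  timexes <- lapply(seq_along(tes), function(i) {
    te <- tes[[i]]
    timex3(tid = paste0("t", i), ttype = te$ttype, value = te$value,
           begin = te$begin, end = te$end, surface = te$surface,
           anchor_tid = if (is.na(te$anchor_idx)) NA_character_ else
             paste0("t", te$anchor_idx))
  })
  validate_document(timex_document(text, timexes, doc_id = doc_id))
}

#' Write a corpus as inline-TimeML files plus a manifest
#'
#' @param corpus list of `timex_document`s.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(corpus, function(doc) {
    path <- file.path(dir, paste0(doc$doc_id, ".xml"))
    writeLines(write_timeml(doc), path, useBytes = FALSE)
    path
  }, character(1))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_docs = length(corpus),
         n_tes = sum(vapply(corpus, function(d) length(d$timexes), integer(1))),
         files = basename(files)),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a corpus of inline-TimeML files
#'
#' @param dir directory of `.xml` fragment files.
#' @return list of `timex_document`s.
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  lapply(files, function(f) {
    read_timeml(paste0(readLines(f, encoding = "UTF-8", warn = FALSE),
                       collapse = "\n"),
                doc_id = sub("\\.xml$", "", basename(f)))
  })
}
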