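# Evaluation: macro-averaged multiclass metrics for type prediction,
# exact-match normalization precision/recall/F1, span-level Type+Value
# accuracy, and the end-to-end synthetic benchmark.

f1_of <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

#' Macro-averaged classification metrics
#'
#' Per-class precision/recall/F1 over the labels present in the gold
#' sequence, averaged uniformly (macro), which insulates the score from class
#' imbalance. Zero-denominator per-class ratios count as 0. The macro F1 is
#' the mean of per-class F1 by default; `mf_mode = "harmonic"` instead takes
#' the harmonic mean of macro precision and macro recall.
#'
#' @param gold,pred equal-length character vectors of labels.
#' @param mf_mode `"mean_f1"` (default) or `"harmonic"`.
#' @return list with `MP`, `MR`, `MF` and a `per_class` data.frame.
#' @export
macro_metrics <- function(gold, pred, mf_mode = c("mean_f1", "harmonic")) {
  mf_mode <- match.arg(mf_mode)
  if (length(gold) == 0 || length(gold) != length(pred)) {
    stop("macro_metrics: gold and pred must be non-empty and equal length")
  }
  classes <- sort(unique(gold))
  per <- do.call(rbind, lapply(classes, function(k) {
    tp <- sum(gold == k & pred == k)
    npred <- sum(pred == k)
    ngold <- sum(gold == k)
    p <- if (npred > 0) tp / npred else 0
    r <- if (ngold > 0) tp / ngold else 0
    data.frame(class = k, precision = p, recall = r, f1 = f1_of(p, r),
               support = ngold, stringsAsFactors = FALSE)
  }))
  MP <- mean(per$precision)
  MR <- mean(per$recall)
  MF <- if (mf_mode == "mean_f1") mean(per$f1) else f1_of(MP, MR)
  structure(list(MP = MP, MR = MR, MF = MF, per_class = per),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("macro P=%.4f R=%.4f F1=%.4f\n", x$MP, x$MR, x$MF))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

as_doc_list <- function(x) if (inherits(x, "timex_document")) list(x) else x

#' Exact-match normalization precision/recall/F1
#'
#' A predicted mention counts as correct only when its span (hence surface)
#' and normalized Value exactly match a gold mention. precision =
#' #correct / #normalized-by-the-system, recall = #correct / #gold;
#' zero denominators give 0 by convention.
#'
#' @param gold_docs,pred_docs a `timex_document` or list thereof over the same
#'   underlying texts, in the same order.
#' @return list(precision, recall, f1, counts).
#' @export
normalization_prf <- function(gold_docs, pred_docs) {
  gold_docs <- as_doc_list(gold_docs)
  pred_docs <- as_doc_list(pred_docs)
  stopifnot(length(gold_docs) == length(pred_docs))
  c_value <- 0L; n_te1 <- 0L; n_te2 <- 0L
  for (i in seq_along(gold_docs)) {
    g <- timex_table(gold_docs[[i]])
    p <- timex_table(pred_docs[[i]])
    p <- p[nzchar(p$value), , drop = FALSE]
    n_te1 <- n_te1 + nrow(p)
    n_te2 <- n_te2 + nrow(g)
    gk <- paste(g$begin, g$end, g$value)
    c_value <- c_value + sum(paste(p$begin, p$end, p$value) %in% gk)
  }
  precision <- if (n_te1 > 0) c_value / n_te1 else 0
  recall <- if (n_te2 > 0) c_value / n_te2 else 0
  list(precision = precision, recall = recall, f1 = f1_of(precision, recall),
       counts = c(C_value = c_value, N_TE1 = n_te1, N_TE2 = n_te2))
}

#' Span-level Type + Value accuracy
#'
#' Evaluation restricted to gold mention spans (no extraction involved): a
#' gold mention is correct when the prediction at the same span has both the
#' right Type and the right Value.
#'
#' @param gold_docs,pred_docs documents over the same texts; predictions
#'   normally come from [predict_on_gold_spans()].
#' @return list(accuracy, counts = c(Correct, N_TE)).
#' @export
normalization_accuracy <- function(gold_docs, pred_docs) {
  gold_docs <- as_doc_list(gold_docs)
  pred_docs <- as_doc_list(pred_docs)
  stopifnot(length(gold_docs) == length(pred_docs))
  correct <- 0L; n_te <- 0L
  for (i in seq_along(gold_docs)) {
    g <- timex_table(gold_docs[[i]])
    p <- timex_table(pred_docs[[i]])
    n_te <- n_te + nrow(g)
    if (nrow(g) == 0 || nrow(p) == 0) next
    j <- match(paste(g$begin, g$end), paste(p$begin, p$end))
    ok <- !is.na(j) & g$ttype == p$ttype[j] & g$value == p$value[j]
    correct <- correct + sum(ok)
  }
  list(accuracy = if (n_te > 0) correct / n_te else 0,
       counts = c(Correct = correct, N_TE = n_te))
}

#' Type + normalization prediction on gold spans
#'
#' Re-annotates a gold document keeping its spans: types are predicted by the
#' classifier, values recomputed by the normalizer (with or without learned
#' correction patterns). This is the setting for comparing rule-only against
#' rule+pattern normalization without extraction effects.
#'
#' @param gold_doc a gold `timex_document`.
#' @param model fitted `type_model`.
#' @param patterns pattern data.frame or `NULL` (rules only).
#' @param lexicons anchor lexicons.
#' @param tagger,triggers feature ports.
#' @return a predicted `timex_document` over the same spans.
#' @export
predict_on_gold_spans <- function(gold_doc, model, patterns = NULL,
                                  lexicons = load_lexicons(),
                                  tagger = default_tagger(),
                                  triggers = load_triggers()) {
  doc <- timex_document(gold_doc$text, doc_id = gold_doc$doc_id)
  if (length(gold_doc$timexes) == 0) return(doc)
  vecs <- lapply(gold_doc$timexes, function(tx) {
    build_vector(tx$surface, tagger, triggers)
  })
  types <- predict_types(model, vecs)
  doc$timexes <- lapply(seq_along(gold_doc$timexes), function(i) {
    tx <- gold_doc$timexes[[i]]
    timex3(tid = tx$tid, ttype = types[i], value = "", begin = tx$begin,
           end = tx$end, surface = tx$surface)
  })
  normalize_document(doc, patterns, lexicons)
}

#' End-to-end synthetic benchmark
#'
#' Generates seeded training and test corpora, learns anchor-equality
#' patterns and fits the type classifier on the training half, then measures
#' on the test half: extraction recall against gold spans, classifier holdout
#' macro metrics, exact-match normalization P/R/F1 of the full annotate
#' pipeline, and span-level accuracy with rules only versus rules plus
#' learned patterns.
#'
#' @param n_train,n_test corpus sizes.
#' @param seed master seed; training and test corpora derive distinct streams.
#' @param cfg_overrides named list of [gen_config()] fields to override.
#' @param classifier a [classifier_config()].
#' @param quiet suppress per-mention normalization warnings.
#' @return list of results (see Details).
#' @export
run_benchmark <- function(n_train = 225L, n_test = 225L, seed = 1L,
                          cfg_overrides = list(),
                          classifier = classifier_config(seed = seed),
                          quiet = TRUE) {
  mk_cfg <- function(n, s) {
    do.call(gen_config, utils::modifyList(list(n_docs = n, seed = s),
                                          cfg_overrides))
  }
  train <- generate_corpus(mk_cfg(n_train, seed))
  test <- generate_corpus(mk_cfg(n_test, seed + 100003L))
  rules <- load_rules()
  lexicons <- load_lexicons()
  triggers <- load_triggers()
  tagger <- default_tagger()

  patterns <- learn_patterns(train, miner_config(), "NORM_ANCHOR_EQUALS", rules)
  model <- fit_type_classifier(corpus_vectors(train, tagger, triggers), classifier)

  gold_tab <- lapply(test, timex_table)
  # extraction recall on gold spans
  found <- 0L; total <- 0L
  for (i in seq_along(test)) {
    sp <- extract_spans(test[[i]]$text, rules)
    gk <- paste(gold_tab[[i]]$begin, gold_tab[[i]]$end)
    total <- total + length(gk)
    found <- found + sum(gk %in% paste(sp$begin, sp$end))
  }
  # classifier holdout
  test_vecs <- corpus_vectors(test, tagger, triggers)
  gold_types <- vapply(test_vecs, `[[`, character(1), "label")
  pred_types <- predict_types(model, test_vecs)
  cls_report <- macro_metrics(gold_types, pred_types)

  run <- function(expr) if (quiet) suppressWarnings(expr) else expr
  pred_docs <- run(lapply(test, function(doc) {
    annotate(doc$text, model, patterns, lexicons, rules, doc_id = doc$doc_id,
             tagger = tagger, triggers = triggers)
  }))
  prf <- normalization_prf(test, pred_docs)

  gold_rule <- run(lapply(test, predict_on_gold_spans, model = model,
                          patterns = NULL, lexicons = lexicons,
                          tagger = tagger, triggers = triggers))
  gold_patt <- run(lapply(test, predict_on_gold_spans, model = model,
                          patterns = patterns, lexicons = lexicons,
                          tagger = tagger, triggers = triggers))
  acc_rule <- normalization_accuracy(test, gold_rule)
  acc_pattern <- normalization_accuracy(test, gold_patt)

  list(
    patterns = patterns,
    extraction_recall = found / total,
    classifier = cls_report,
    normalization = prf,
    accuracy_rule = acc_rule$accuracy,
    accuracy_rule_pattern = acc_pattern$accuracy,
    mean_tes_per_doc = mean(vapply(c(train, test),
                                   function(d) length(d$timexes), integer(1)))
  )
}
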