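# zhtimex

Extraction, classification and ISO 8601 normalization of temporal
expressions (TIMEX3) in Chinese narrative clinical text.

Discharge summaries and other Chinese EMR narratives are full of temporal
expressions — absolute dates (`2014年10月13日`), clock times
(`7:48:16`), durations (`两年五个月`), relative references (`6天前`),
recurring schedules (`第7、10、14天`) and deictics (`目前`). Building a
clinical timeline from such text requires finding these spans, typing them
(TimeML `DATE` / `TIME` / `DURATION` / `SET`), resolving the *reference
time* each relative expression depends on, and computing an ISO 8601
`Value`. zhtimex implements that pipeline for researchers working on
clinical NLP and temporal information extraction:

- **extraction** by an editable heuristic rule inventory plus learned
  context patterns, overlaps resolved longest-match-first;
- **type classification** from four feature groups (POS bag over a
  replaceable tagger port, trigger terms, trigger positions, a TIME
  indicator) with a pluggable classifier registry — the default composes a
  seeded Gaussian random projection with 1-nearest-neighbour;
- **anchor resolution** by three prioritized strategies: a critical clinical
  event (入院/出院/手术/化疗/返院) in the same sentence with a known
  occurrence time, the section phrase opening the paragraph (出院医嘱,
  出院情况, …), else the nearest direct mention;
- **normalization** with calendar-aware arithmetic (month clamping, week =
  7 days, hour offsets floored to days against date references) and
  **anchor-equality correction patterns** mined from annotated corpora with
  support/confidence ≥ 0.8 filtering and substring reduction — catching
  constructions like 术后3月余 whose correct value *is* the reference time;
- a **seeded synthetic discharge-summary generator** with gold annotations
  (the evaluation corpora of this field are private hospital records), and
  an **evaluation suite**: macro-averaged classification metrics,
  exact-match normalization P/R/F1, and span-level Type+Value accuracy.

## Worked example

Train on a synthetic corpus, then annotate a note:

```r
library(zhtimex)

corpus <- generate_corpus(gen_config(n_docs = 40, seed = 7))
model  <- fit_type_classifier(corpus_vectors(corpus), classifier_config(seed = 7))
pats   <- learn_patterns(corpus)
pats
#>         template            purpose support confidence
#> 1    <TIMEX3>余, NORM_ANCHOR_EQUALS      40          1
#> 2     <TIMEX3>患 NORM_ANCHOR_EQUALS      40          1
#> 3    况:<TIMEX3> NORM_ANCHOR_EQUALS      40          1
#> 4 术后<TIMEX3>余 NORM_ANCHOR_EQUALS      40          1
#> 5 癌术后<TIMEX3> NORM_ANCHOR_EQUALS      40          1

note <- paste0("入院日期:2014-10-11\n出院日期:2014-10-23\n",
  "患者6天前出现乳房肿物。于2014年10月13日行右乳癌改良根治术。\n",
  "主诉:右乳腺癌术后3月余,返院行化疗。\n",
  "出院医嘱:1、72小时后自行拆除绷带;2、不适随诊。\n")
annotate(note, model, pats, doc_id = "note1")
#> <timex_document note1> 114 chars, 6 timexes
#>   t1 DATE     2014-10-11             2014-10-11
#>   t2 DATE     2014-10-23             2014-10-23
#>   t3 DATE     2014-10-17             6天前 -> t2
#>   t4 DATE     2014-10-13             2014年10月13日
#>   t5 DATE     2014-10-13             3月 -> t4
#>   t6 DATE     2014-10-26             72小时后 -> t2
```

Reading the output: `6天前` (six days ago) anchors to the discharge date
2014-10-23 and normalizes to 2014-10-17; `3月` in the chief complaint
术后3月余 matches the learned template `术后<TIMEX3>余`, so its value is
*corrected to* the surgery date 2014-10-13 instead of being read as a month
reference; `72小时后` (72 hours later) inside the discharge instructions
anchors to the discharge date via the section phrase 出院医嘱 and floors to
+3 days. `write_timeml()` serializes the document back to inline
`<TIMEX3 …>` markup; `read_timeml()` parses it, round-trip exact.

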