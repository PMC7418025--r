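---
title: "Normalizing temporal expressions in Chinese clinical text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing temporal expressions in Chinese clinical text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zhtimex)
```

## The problem

Narrative Chinese clinical documents — discharge summaries above all — are
dense with temporal expressions (TEs): admission and discharge dates, clock
times of examinations, durations of symptoms, relative references ("6天前",
six days ago), recurring instruction schedules ("第7、10、14天", on days 7,
10 and 14), and deictics ("目前", at present). Turning these into
machine-readable timeline entries requires three steps:

1. **extraction** — finding the character spans that denote time;
2. **type classification** — assigning each span one of the four TimeML
   TIMEX3 types `DATE`, `TIME`, `DURATION`, `SET`;
3. **normalization** — computing an ISO 8601 `Value` for each span, which for
   relative, deictic and set expressions first requires resolving a
   *reference time* (the TIMEX3 `anchorTimeID`).

zhtimex represents a document as a triple of mention surfaces, their type
attributes, and their normalized values, annotated inline as
`<TIMEX3 tid Type Value anchorTimeID>…</TIMEX3>`.

## Pipeline

### Extraction

A shipped rule inventory (JSON, editable without code changes) covers the
surface families observed in discharge summaries: absolute dates
(`2014年6月3日`, `2014-06-03`, `2014/6/3`, day-month forms like `22/9`),
clock times (`上午7点20分4秒`, `7:48:16`), relative offsets
(`N{年|月|周|天|小时|…}{前|后}`), durations with Chinese or Arabic numerals
(`两年五个月`, `1年余`), enumerated day sets (`第7、10、14天`) and deictics.
Chinese numerals are recognized up to 99; larger magnitudes require Arabic
digits. Overlaps are resolved longest-match-first with ties to the leftmost
span, so `2014/10/11 7:48:16` is one TIME span, not a date plus a clock.
Learned extraction patterns may *add* spans their context template matches
(the placeholder is matched by a bounded run of temporal characters), but can
never displace a rule-produced span.

Two deliberate extraction choices deserve note. First, the approximation
marker 余 ("more than") is absorbed into a duration span only at the end of a
phrase (`1年余。`); elsewhere it is treated as context, so `术后3月余,` yields
the span `3月` with 余 as right context. This keeps the anchor-equality
context (below) learnable, at the cost of occasionally splitting an
approximation marker from its numeral. Second, bare 现/今 are matched only
with negative look-behinds, because 发现/出现 are ubiquitous in clinical
prose.

### Type classification

Each span is encoded by four feature groups computed over its surface: a
part-of-speech bag from a replaceable tagger port (the shipped tagger is
lexicon-based, distinguishing year-like four-digit numbers, other Arabic
numbers, Chinese numerals, temporal nouns, the measure word 个, ordinal 第,
localizers 前/后, and approximation markers — so the package tests offline;
an adapter to an external Chinese tagger can be dropped in); trigger terms
from a shipped lexicon (年 月 日 周 小时 点 分 秒 次 每 前 后 第 …); the
first-occurrence character offset of each trigger ("trigger position" is not
otherwise defined, so the simplest deterministic reading is used); and a
boolean TIME indicator that fires on clock features (colon-separated digit
pairs, 点/时 followed by digits, day-part words). POS features cover the
surface only, not its context: the feature definitions are ambiguous about a
context window, and surface-only keeps vectors a pure function of the
surface.

The default classifier composes a seeded Gaussian random projection (default
32 dimensions — a repository default; when the observed feature space is
smaller, the projection reduces to the identity) with a 1-nearest-neighbour
rule under Euclidean distance, ties broken by smallest training index. This
mirrors the observation that mentions of the same type in discharge
summaries are near-duplicates of one another, so nearest-neighbour
classification over a dimensionality-reducing filter is both accurate and
cheap. Plain KNN and multinomial logistic regression are registered as
alternatives; everything is bit-reproducible given data, configuration and
seed.

### Reference-time resolution

A mention is *direct* when its type is not `DURATION` and its surface is a
complete absolute date or datetime; direct mentions normalize without any
reference. Everything else (except anchor-free durations) needs an anchor,
resolved by three strategies in priority order:

1. **Critical event** — a clinical milestone mention (入院, 出院, 手术/术后,
   化疗, 返院/回院) in the same sentence whose occurrence time is known. The
   occurrence time of an event kind is taken from a direct mention sharing a
   sentence with an event mention anywhere in the document, falling back to
   the structured header lines (入院日期/出院日期). When several event
   mentions share the sentence, the one nearest to the mention (character gap
   between spans) with a known time wins. A section phrase opening the
   sentence (e.g. the 出院 inside 出院医嘱:) is a discourse marker, not an
   event mention, and is skipped — this is what makes "72小时后" inside
   discharge instructions anchor to the discharge date rather than to the
   word 出院 in the section header.
2. **Section phrase** — the enclosing paragraph (a line of text) opens with a
   known section phrase followed by a colon (出院医嘱, 出院情况, 入院诊断,
   …), each conventionally anchored to an event kind.
3. **Nearest direct mention** — by distance between span starts, preceding
   preferred over following, preceding preferred on ties.

Resolution is a pure function of the document, so it is computed against a
per-document context cache (sentence/paragraph segmentation, event table).

### Normalization

- Relative offsets use calendar-aware arithmetic: weeks are seven days;
  month offsets clamp the day of month (March 31 minus one month is
  February 28); hour/minute/second offsets against a date-only reference
  floor to whole days (72小时后 is +3 days), while a datetime reference gets
  full clock arithmetic. Deictics return the reference unchanged. 余/约/多
  set an approximation flag but do not change the value (no TimeML `MOD`
  attribute is emitted).
- Month-only references ("2月" typed DATE) resolve to (reference year,
  month) at month precision; day-month slash forms follow the D/M convention
  seen in the data (`22/9` is 22 September of the reference year).
- Day sets count the event day as day 1: 第k天 maps to reference + (k−1)
  days. The day-index convention is not fixed by any source; day-1 was
  chosen and is stated here so it can be audited.
- Durations drop the approximation marker; pure-week durations serialize as
  `PnW`, mixed durations convert weeks to days since ISO 8601 forbids mixing
  the week designator.
- Output precision follows the reference for offset arithmetic, and the unit
  for month-only/year-only surfaces.

### Anchor-equality patterns

Heuristic anchoring alone mis-handles mentions whose correct value *is* the
reference time, e.g. the chief-complaint construction
主诉:右乳腺癌术后3月余,返院… — the mention "3月" should carry the surgery
date itself, not an offset from the return-to-hospital event. The miner
learns short character templates around such mentions:

1. identify mentions whose gold Value equals their anchor's gold Value;
2. substitute each with the placeholder `<TIMEX3>`;
3. enumerate every contiguous template containing the placeholder up to the
   maximum length (default 6 characters, placeholder counted as one — the
   unique small calibration under which the documented example sentence
   遂于`<TIMEX3>`行右乳癌改良根治术 yields exactly 15 candidates: left
   context 2, right context 9, 6+5+4);
4. score each candidate corpus-wide: `support` = matching sites,
   `confidence` = correct sites / matching sites. For anchor-equality
   patterns a site is a gold mention whose context matches; it is correct
   when that mention's Value equals its anchor's Value. For
   extraction-purpose patterns the sites are rule-proposed candidate spans
   plus gold spans, correct when the site is a gold span (the site semantics
   are this package's definition, chosen as the reading under which
   confidence is informative for both purposes);
5. keep patterns with confidence ≥ 0.8 (the threshold is inclusive);
6. remove any kept pattern that has a kept strict-substring pattern with
   confidence at least as high — the shorter, more general template
   survives unless the longer one is strictly more confident. (The
   reduction could equally be run in the other direction; resolving toward
   generality is this package's choice, since a more general template with
   equal confidence covers every site its superstring covers.)

At annotation time, if any learned template matches a mention's context, the
mention's value is overridden with its anchor's value, longest template
first. Patterns matching at character level can mis-fire: an over-general
context like `<TIMEX3>于我` will override a correctly computed offset value
— the test suite reproduces this failure mode deliberately.

Mining is performed character-level, without word segmentation: the useful
templates are one-to-three character contexts, below the granularity at
which segmentation helps.

## The synthetic corpus

The evaluation corpora of clinical temporal-normalization studies are
private hospital records, so the package ships a seeded generator that emits
discharge summaries with gold annotations correct by construction
(template-based; no language model). Each document has header date lines, a
diagnosis section, a narrative with surgery/chemotherapy sentences carrying
direct dates and a datetime, duration mentions (including contexts that
deliberately share characters with the planted template — 术后N天…,
出院后N周余… — so that sub-templates of the planted context score below
threshold), an anchor-equal chief complaint (default context 术后…余), a
discharge-status deictic, and discharge instructions with a day set and an
hour offset.

Defaults are fixed once: 13.4 mentions per document in expectation (12 from
the backbone plus a Poisson number of extras), matching the density of
annotated discharge summaries; the extras' type mix 0.70/0.10/0.15/0.05
over DATE/TIME/DURATION/SET and the 0.35 anaphoric fraction among extra
DATE mentions are repository defaults, chosen as plausible for clinical
narrative and configurable; `typo_rate` injects the real-world
出院日期:出院日期 header corruption; `planted_pattern_rate` controls how
often the anchor-equal mention appears in the fixed template context. Gold
anchors come from the generator's own bookkeeping of template semantics (the
resolver is a second, independent implementation of the same conventions),
and gold anaphoric values are computed from those anchors with the package's
calendar arithmetic.

What the generator does *not* emulate — and therefore what green tests do
not establish about real records: misspelled or free-form date formats
beyond the inventoried families, enumerated series without specific times
(门诊 星期一 星期二 … 上午), nested or discontinuous mentions, conflicting
event dates, cross-document anchors, and genuinely ambiguous "2月"-style
month/duration surfaces whose resolution needs discourse context. On clean
synthetic data the pipeline is exact (the acceptance run measures exact-match
F1 = 1.0 at 450 + 450 documents); real hospital text contains all of the
phenomena listed above and must be expected to score substantially lower —
that gap is the honest summary of what template-generated data can and
cannot show.

## Evaluation conventions

Type prediction is scored with macro-averaged precision, recall and F1 over
the labels present in the gold sequence, because clinical type distributions
are heavily imbalanced; zero-denominator per-class ratios count as 0, and
the macro F1 is the mean of per-class F1 (the harmonic-of-means alternative
coexists in the literature and is available behind a flag). Normalization is scored exact-match: a prediction counts only
when span and Value both equal a gold mention; precision divides by mentions
the system normalized, recall by gold mentions. The rule-only versus
rule+pattern comparison is run on gold spans with predicted types, scored by
accuracy requiring Type and Value both correct — isolating the contribution
of the learned patterns from extraction effects.

## Numerical and engineering choices

- Problem sizes: the acceptance script and the end-to-end test use 450
  training and 450 testing documents (the split sizes of the motivating
  annotation study); property suites use 100–200 random cases per property
  under fixed seeds.
- Values are timezone-free throughout; none occur in the domain.
- The SET `Value` serialization (a bracketed, comma-joined list of ISO
  dates) is this package's own: no uncorrupted reference serialization was
  available, and the parser accepts exactly the writer's form.
- The writer always zero-pads months and days; the parser is lenient and
  accepts unpadded fields ("2014-2").
- tids are assigned in document order starting at t1; attribute order is
  fixed (tid, Type, Value, anchorTimeID) so serialization is byte-stable.
- Inline TimeML is scanned with a dedicated single-tag reader rather than an
  XML parser: clinical narrative with inline tags is not XML-escaped text,
  and the vocabulary here is exactly one tag.
- Per-mention normalization failures warn and emit an empty Value rather
  than aborting a document; an empty Value is counted against recall but
  not precision, which mirrors how a deployed system degrades.

## Known limitations

Errors compound along the pipeline: a type misclassification routes a
mention to the wrong normalization family (a "2月" typed DATE instead of
DURATION produces a month reference instead of P2M), and no joint decoding
is attempted. Pattern matching is purely character-based and will mis-fire
on coincidental contexts. The extraction inventory is a reconstruction from
printed examples, not an exhaustive grammar of Chinese temporal language;
generalizing beyond the inventoried families requires editing the shipped
JSON rule file. Chinese numeral parsing stops at 99.
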