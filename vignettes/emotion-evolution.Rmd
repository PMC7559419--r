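---
title: "Modelling event-driven public emotion evolution on microblogs"
author: "emovolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling event-driven public emotion evolution on microblogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emovolve)
```

## The problem

During a long-running epidemic, public mood on microblogging platforms is
not a single sentiment score: it is a *distribution* over fine-grained
emotions (joy, anger, sadness, fear, disgust, love, surprise, and 21
sub-emotions beneath them) that shifts as events unfold — case
announcements, policy changes, the death of a public figure. emovolve
implements a reproducible pipeline for tracking that distribution day by
day, anchoring it to the epidemic's own timeline, and relating it to the
trending events that plausibly drive it.

The pipeline is entirely lexicon-based: no trained classifier, no
segmentation model, no network access. Every stage is a deterministic
function of its inputs, and a seeded synthetic-corpus generator provides
planted ground truth for every stage.

## Emotion scoring

Posts within a calendar day (in a configurable time zone, default UTC+8)
are concatenated into one document; the corpus becomes
$D = \langle d_1, \dots, d_k \rangle$ with one document per day. Emotion
words are located with **leftmost-longest dictionary matching** against the
lexicon: at each character position the longest lexicon word starting there
is accepted and the scan resumes after it. This makes matching a pure
function of (text, lexicon) — reproducible without committing to any
third-party word segmenter — at the cost of ignoring context (see
Limitations). Text is NFC-normalised first; an optional substitution table
converts emoji to bracketed tokens before matching.

For an emotional term $w_i$ in document $d_j$:

$$tf_{ij} = \frac{n_{i,j}}{\sum_p n_{p,j}}, \qquad
  idf_i = \log\frac{|D|}{df_i + 1}, \qquad
  tfIdf(w_i, d_j) = tf_{ij} \cdot idf_i$$

with natural logarithm (the base is a pure rescaling here; it is fixed and
recorded in every run's resolved configuration). Each lexicon word carries
a degree level $L(w) \in \{1,3,5,7,9\}$, and the day's emotion distribution
at category resolution is

$$Ratio(c) = \frac{\sum_{w \in d_j,\ cat(w)=c} L(w)\,tfIdf(w,d_j)}
                  {\sum_{w \in d_j} L(w)\,tfIdf(w,d_j)},$$

stacked into a $k \times 7$ matrix (or $k \times 21$ at sub-emotion
resolution). Because numerator terms are a partition of the denominator,
category ratios always equal the sum of their sub-emotion ratios, and
non-empty rows sum to exactly 1.

**The negative-idf regime.** The $+1$ smoothing makes $idf$ slightly
negative for a term present in *every* document. We retain negative values
rather than clamping them — fidelity to the formula over ad-hoc correction —
with two documented consequences. If the whole denominator becomes
non-positive the row carries no usable signal: it is flagged empty with a
warning and excluded downstream. If idf signs are merely mixed, individual
ratios can leave $[0,1]$ while still summing to 1. Neither regime arises
when the lexicon is large relative to daily term draws (document
frequencies then stay below $|D|$), which is the situation with realistic
vocabularies of thousands of phrases; it is characteristic of toy lexicons
only. The synthetic generator's default lexicon size (150 words per
sub-emotion, 3150 words) is chosen to reproduce the realistic regime.

**Accumulated emotion** deliberately drops idf, so days with very
different post volumes remain comparable:

$$Acc_j(c) = \sum_{w \in d_j,\ cat(w)=c} L(w)\, tf_{wj} \in [0, 9].$$

Whether a reader wants per-day values or their running sum differs by use;
both are emitted (`cumulative` flag).

## The epidemic skeleton and phases

The *skeleton* is the per-day pair (newly confirmed cases, accumulated
confirmed cases), extracted from post text by configurable patterns with
one capture group per dimension; defaults cover the common Chinese
announcement forms, with full-width digits, thousands separators and the
×10⁴ *wan* suffix normalised. When a day carries several announcements
the largest value is retained — official counts are revised upward within a
day. Missing days get `NA`.

Phase segmentation cuts the timeline at change points of the new-case
series. `auto` mode fills gaps by last observation carried forward,
applies a centred moving average (window 3 by default; 1 disables), and
takes interior local extrema of the plateau-compressed series as breaks —
a deliberately minimal mechanisation of picking peaks and valleys by
inspection, not a model-based change-point detector. `manual` mode accepts
explicit break dates (a break date ends its phase), which is how published
phase boundaries are reproduced exactly: breaks at 4 and 12 February 2020
on a 21 January–17 February window give phases of 15, 8 and 5 days.
Narrative accounts of when growth "peaked" can disagree with the break
dates actually used for analysis (2 versus 4 February in the source
literature for this design); manual mode sidesteps the ambiguity and the
discrepancy is surfaced here rather than resolved.

## Evolution models

Within each phase, **covariance** is the Pearson correlation between every
pair of emotion Ratio series over the phase's non-empty days (at least 3
required; series constant within a phase give flagged-undefined entries).

The **transition model** works on ranks, which removes the large base-rate
imbalance between emotions: each day's distribution becomes a strict
permutation of ranks 1–7 (ties broken by the fixed category order — a
choice forced by the conservation laws below). For each consecutive pair of
non-empty days, cell $T(x,y)$ is incremented when emotion $y$ holds at day
$i{+}1$ the rank emotion $x$ held at day $i$; per-pair matrices are summed
over the phase. The diagonal counts rank retention ("stability"). Because
every pair contributes one permutation match per rank, every row and
column of $T$ sums to the number of day pairs — an invariant the test
suite checks exhaustively.

The cell-indexing convention deserves a note: a transition count indexed
by *emotion pair* via rank matching (as here) and one indexed by *rank
pair* are related by a permutation, and published descriptions do not
always distinguish them. We use emotion-pair indexing because the
per-emotion "stability" diagonal only makes sense there.

Empty days are skipped and pairs are formed between consecutive non-empty
days within a phase only; days belong to exactly one phase and no
cross-phase pairs are formed.

## Hot events

Super topics are scored per day and user group by rank fusion over five
engagement measures: post-level mean retweets, comments and likes, and
topic-level discussion and read counters (cumulative platform snapshots,
so the per-day maximum is used). Each measure is ranked across the day's
topics with competition ("min") ties — this keeps the all-rank-1 lower
bound exact and is scale-free — and

$$hot(e) = w_1\,\|rank(\bar H_e)\|_1 + w_2\,\|rank(S_e)\|_1,
  \qquad w_1 = w_2 = 0.5.$$

Lower is hotter; the hottest event is the argmin. The structural
imbalance — three ranks on one side, two on the other, equal weights — is
retained as stated; a normalised variant (each side divided by its rank
count) sits behind `normalize = TRUE`, off by default. The number of
events extracted per day (`top_k`) is a parameter: published analyses use
both top-2 and top-3.

Users are split into *large* and *common* groups by whether any of their
posts drew strictly more than 1000 comments; the two groups are analysed
as separate corpora over a shared skeleton, since the epidemic timeline is
common while attention differs.

## Corpus handling choices

* Day boundaries follow a configurable time zone, default UTC+8 (the
  studied platform's home zone); the bucketing unit is the calendar day.
* Date windows are inclusive at both ends.
* The cleaning order applies the date window first and counts super-topic
  sizes *inside* it (topics with fewer than 50 posts are dropped; exactly
  50 is kept). This order is idempotent — re-filtering a filtered corpus
  changes nothing, because the topic filter drops whole topics without
  shrinking survivors — and matches the row order of the source data-set's
  cleaning table. The alternative reading (topic sizes counted on the raw
  corpus) is available via `topic_filter_first = TRUE` but is not
  idempotent, which is why it is not the default.
* Empty days stay in the timeline (flagged) to preserve alignment with the
  skeleton, and are excluded from covariance/transition computation.
* One label per lexicon word is enforced; source ontologies do not clearly
  license multi-label words and a single label keeps Ratio a partition.

## The synthetic generator

`generate_corpus()` emulates the statistical structure the analysis
assumes, with every quantity planted and recoverable:

* **Scale.** 58 days ending 17 February 2020 (so the 21 January–17
  February analysis window sits inside), Poisson post volumes of 200
  posts/day for ~500 common users and 10 posts/day for ~20 large users.
* **Text.** Each post draws emotion words from the day's planted category
  mixture (uniform within category) interleaved with filler tokens from a
  disjoint alphabet, so true term counts are exactly recoverable; all
  synthetic words share one character length, so none is a substring of
  another. Mixture weights drift linearly from a fear-dominant to a
  love-dominant profile by default and are specified directly (not
  sampled), so recovery targets are exact inputs.
* **Engagement.** Log-normal with a large-group location scale of 1000×
  (mirroring the 2–3 orders of magnitude separating official accounts from
  ordinary users in real engagement tables); at least one large-group post
  is guaranteed past the 1000-comment threshold. Topic-level counters grow
  linearly with elapsed days, as cumulative platform counters do.
* **Epidemic curve.** Deterministic: quiet lead-in, quadratic rise from a
  10 January onset to a 12 February peak of 3000 new cases/day, linear
  decline; accumulated counts are the running sum. Each day embeds one
  announcement post in the default pattern language (probability
  configurable).

What the generator does **not** emulate: linguistically coherent text,
negation and sarcasm, reply cascades, bot accounts, regional structure,
day-of-week seasonality. Passing recovery tests therefore demonstrates the
pipeline's correctness and signal-recovery behaviour under its stated
assumptions, not robustness to the full messiness of real microblog text.

## Numerical and engineering notes

* Determinism: all randomness flows through a single integer seed; file
  outputs are byte-identical across reruns with identical inputs
  (timestamps are logged to stderr only, never into artifacts).
* Ties: emotion ranking breaks ties by fixed category order; hot-degree
  ranking uses competition ranks; hottest-event ties fall back to larger
  post count, then lexicographic topic name.
* Degenerate inputs: empty documents, empty engagement tables and
  insufficient per-phase data produce flagged/empty results or named
  errors, never silent zeros; the pipeline logs and skips phases with too
  few usable days rather than aborting a whole run.
* Problem sizes in the test suite were chosen to exercise every code path
  briskly: oracle comparisons use corpora of up to 5 documents and 20
  terms, conservation laws are checked on 100 random rank sequences of up
  to 30 days, and end-to-end recovery runs on the generator's default
  58-day and 30 × 200-post corpora.

## Limitations

Dictionary matching cannot see negation ("not happy"), sarcasm, or
context; emotion attribution is purely lexical. The idf smoothing
convention makes tiny-vocabulary corpora degenerate (see above). The
change-point scan is intentionally simple — series with noise-induced
micro-extrema should be smoothed or segmented manually. Engagement-based
hot degrees measure attention, not approval. All findings on synthetic
corpora inherit the generator's assumptions listed above.
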