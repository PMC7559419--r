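# emovolve

Event-driven tracking of public emotion evolution on microblogs during an
epidemic.

Public mood during a long crisis is a moving distribution over fine-grained
emotions, driven by events: case announcements, policy changes, the death of
a public figure. emovolve is an R package for analysts of social-media
corpora (infodemiology, disaster psychology, computational social science)
that turns a stream of microblog records into:

* a per-day **complex-emotion matrix** over 7 emotion categories (joy,
  anger, sadness, fear, disgust, love, surprise) and 21 sub-emotions,
  scored by degree-weighted lexicon tf-idf,
* the **epidemic skeleton** — daily new/accumulated confirmed-case counts
  extracted from announcement text — and a segmentation of the timeline
  into **phases** at its change points,
* phase-wise **emotion covariance** (Pearson) and rank-based **emotion
  transition matrices** (which emotion takes over which emotion's rank
  between consecutive days; the diagonal measures stability),
* **hot events**: rank-fusion scoring of super topics over five engagement
  measures, per day and per user group (large vs common accounts).

## The model in brief

For emotional term $w_i$ in the day-$j$ document, with degree level
$L(w) \in \{1,3,5,7,9\}$ from the lexicon:

$$tf_{ij} = \frac{n_{i,j}}{\sum_p n_{p,j}},\quad
  idf_i = \log\frac{|D|}{df_i+1},\quad
  Ratio(c) = \frac{\sum_{cat(w)=c} L(w)\,tf\,idf}{\sum_{w} L(w)\,tf\,idf}$$

Accumulated emotion per day is the idf-free
$Acc(c) = \sum_{cat(w)=c} L(w)\,tf_{wj}$. Daily distributions are converted
to rank permutations; transition cell $T(x,y)$ counts, over consecutive
days in a phase, emotion $y$ occupying the rank emotion $x$ held the day
before. Super-topic hot degree is
$hot(e) = w_1\|rank(\bar H_e)\|_1 + w_2\|rank(S_e)\|_1$ with
$w_1 = w_2 = 0.5$ (lower = hotter; the hottest event is the argmin).

A fully seeded synthetic generator (`generate_lexicon()`,
`generate_corpus()`, `simulate_dataset()`) produces corpora with planted
mixtures, epidemic curves, engagement scales and boosts, so every stage is
testable against ground truth without platform access. Details and design
rationale are in the methods vignette,
`vignettes/emotion-evolution.Rmd`.

## Worked example

Simulate the default 58-day study conditions, run the full pipeline on the
21 January – 17 February analysis window with the published phase breaks,
and summarise:

```r
library(emovolve)
sim <- simulate_dataset("demo", seed = 1, config = generator_config(seed = 1))
cfg <- pipeline_config("demo/corpus.jsonl", "demo/lexicon.tsv", "demo/out",
                       min_topic_posts = 50,
                       date_start = "2020-01-21", date_end = "2020-02-17",
                       phase_mode = "manual",
                       manual_breaks = as.Date(c("2020-02-04", "2020-02-12")))
res <- run_pipeline(cfg)
tail(res$skeleton, 4)
#>          date n_new n_acc
#> 25 2020-02-14  2280 39434
#> 26 2020-02-15  1920 41354
#> 27 2020-02-16  1560 42914
#> 28 2020-02-17  1200 44114
res$phases
#>    label      start        end
#> 1 phase1 2020-01-21 2020-02-04
#> 2 phase2 2020-02-05 2020-02-12
#> 3 phase3 2020-02-13 2020-02-17
round(tail(unclass(res$cat_matrix_common), 3), 3)
#>              joy anger sadness  fear disgust  love surprise
#> 2020-02-15 0.150 0.072   0.111 0.123   0.158 0.330    0.057
#> 2020-02-16 0.143 0.062   0.195 0.107   0.141 0.292    0.060
#> 2020-02-17 0.147 0.069   0.156 0.102   0.108 0.357    0.061
```

The skeleton reproduces the planted epidemic curve (peak 3000 new cases on
12 February, declining after); the breaks give the 15-, 8- and 5-day
phases; and by mid-February the *love* ratio (~0.33–0.36) dominates the
daily emotion distribution, tracking the planted drift from a
fear-dominant to a love-dominant mixture. `summarize_run("demo/out")`
reads the written bundle back and reports, per group and phase, the
strongest covariances, the most stable emotion (here: *love* for common
users in all three phases) and the hottest event per day (dominated by
confirmed-case topics, the most popular catalog entries):

```
[common] phase1 strongest covariance: love ~ sadness (r=-0.659)
[common] phase1 most stable emotion: love (14 retention(s))
...
```

All artifacts (`skeleton.csv`, `phases.json`, per-group emotion and
accumulated matrices, per-phase `covariance_*.csv` / `transition_*.csv`,
`hot_events_*.csv`, `distribution_*.csv`, a resolved config and run log)
are plain CSV/JSON/YAML in `demo/out/`.

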