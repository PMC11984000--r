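# vidunder

Human-in-the-loop understandability classification of patient-education
videos, and a matched-sample analysis of what understandability is worth in
viewer engagement.

## The problem

Most adults look for health information online, yet only a small fraction
have the health literacy to interpret it. Patient-education videos on
user-generated content platforms vary enormously in how understandable they
are, and expert review of every video does not scale. `vidunder` implements
a scalable middle road: expert judgment anchored in the PEMAT instrument
(the AHRQ Patient Education Materials Assessment Tool for audio/visual
materials), amplified by a semi-supervised classifier that asks a human only
when its two views of a video disagree.

The package covers four stages:

1. **PEMAT scoring.** The audio/visual understandability form has 12 items
   scored agree (1) / disagree (0), seven of which also admit
   "not applicable". The understandability score is

   *score = 100 × (items scored 1) / (items not N/A)*,

   and a video is *high understandability* exactly when the score is
   strictly greater than 50%.

2. **Two-view feature extraction.** Each video yields a 12-feature
   *metadata view* (title/description/tags flags, description readability,
   active-voice, summary-phrase, transition-phrase and medical-term counts,
   duration, word statistics) and a 12-feature *content view* (narrative
   readability and counts, transcription and OCR confidences, scene and
   object counts) built from precomputed content signals. Readability is the
   Automated Readability Index by default (Flesch-Kincaid grade is
   selectable); phrase counting is case-insensitive, longest-first and
   non-overlapping at word boundaries; medical terms come from a
   dictionary matcher over six term categories with a pluggable recognizer
   interface.

3. **Co-training with an oracle.** One L2-regularized logistic classifier
   per view is trained on the labeled set L. Unlabeled videos predicted with
   probability ≥ a confidence threshold (default 0.65) by both views with
   the same sign are auto-labeled; confident but *conflicting* predictions
   go to the oracle — a human expert, a file queue, or a simulated expert in
   tests. The loop halts when the pool is empty, nothing new is labeled, or
   an iteration cap is reached; the result is the enlarged labeled set L′,
   both classifiers, and a per-iteration audit log. Final predictions
   average the two views' probabilities.

4. **Engagement impact.** With high understandability as the treatment,
   the package matches treated and control videos on channel and video
   covariates (coarsened exact matching, or 1:1 caliper propensity-score
   matching), reports standardized-mean-difference balance before and
   after, and estimates the average treatment effect (ATE) on
   log-transformed view, like and comment counts by weighted least squares
   of the log outcome on intercept + treatment.

A seeded synthetic-corpus generator with known ground truth (labels, planted
text counts, planted treatment effects) makes every stage testable without
any data download.

## Worked example

```r
library(vidunder)

# score one PEMAT assessment: 7 agree, 3 disagree, 2 N/A
a <- pemat_assessment("vid01", c(1,1,1,1,1,1,1,0,0,0,NA,NA))
understandability_score(a)
#> PEMAT understandability: 70.0% (high; 10 applicable items)

# generate a separable synthetic corpus and co-train
cfg <- synthetic_config(n_videos = 860, seed = 7, confounding = FALSE)
sim <- generate_corpus(cfg)
vm  <- view_matrices(sim$corpus)
truth <- setNames(sim$truth$label, sim$truth$video_id)
ids <- vm$ids; lab <- ids[1:60]; unlab <- ids[61:660]; hold <- ids[661:860]

fit <- cotrain(
  labeled   = list(meta = vm$meta[lab, ], content = vm$content[lab, ],
                   labels = truth[lab]),
  unlabeled = list(meta = vm$meta[unlab, ], content = vm$content[unlab, ]),
  config    = cotrain_config(seed = 7),
  oracle    = oracle_simulated(truth, error_rate = 0, seed = 7)
)
print(fit)
#> Co-trained two-view understandability classifier
#>   labeled set: 660 videos (60 seed)
#>   iterations: 4; halt: no new videos
#>   oracle calls: 7

pred <- predict(fit, list(meta = vm$meta[hold, ], content = vm$content[hold, ]))
evaluate(truth[hold], pred$label, pred$prob)
#> Classification metrics
#>  class precision recall f1 support
#>      0         1      1  1      86
#>      1         1      1  1     114
#> weighted: precision 1.0000, recall 1.0000, F1 1.0000; accuracy 1.0000; AUC 1.0000
```

Only 7 of the 600 unlabeled videos needed a human answer: the rest were
labeled by cross-view agreement. On the held-out 200 videos the co-trained
pair classifies the separable corpus perfectly, slightly ahead of the best
single-view baseline trained on the 60 seed labels alone (weighted F1
0.985 for the metadata view).

A command-line front-end wrapping the same functions ships in
`inst/cli/vidunder` (subcommands `simulate`, `extract-features`,
`score-pemat`, `cotrain`, `evaluate`, `rank`, `ate`).

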