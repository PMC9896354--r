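# famcomm

Lexicon-based scoring and prediction of **openness of family
communication** in hereditary-cancer interview narratives.

People who carry a pathogenic variant associated with hereditary breast
and ovarian cancer (HBOC) are, under most privacy laws, the only channel
through which at-risk relatives learn that they should consider genetic
testing.  How openly a carrier talks about the test result inside the
family is therefore a quantity of real clinical interest.  `famcomm` is
an R toolbox for researchers who have interview transcripts and subject
covariates and want to (a) turn each transcript into a numeric
*openness-of-communication* score and (b) model that score from
narrative sentiment and demographics.

## What it computes

**Openness score.**  Given a hand-scored lexicon of N-grams (unigrams to
trigrams, each scored on the integer scale −3 … +3 for how strongly it
signals open or closed communication), a narrative with token sequence
*t₁ … t_L* is scored

  S = Σ over matched N-grams of score(g),

where matching is greedy longest-match-first, left-to-right,
non-overlapping by default (each token contributes to at most one match;
an "all-matches" policy is available for sensitivity analysis).  Raters
disagreeing about an entry's score are merged by the average rounded to
the greater nearest integer (mean 2.5 → 3, mean −2.5 → −2).

**Sentiment features.**  Per narrative, token counts for the eight
emotion categories (anger, anticipation, disgust, fear, joy, sadness,
surprise, trust) plus positive/negative totals from an emotion-category
lexicon, with *net sentiment = positive − negative*; optional valence
sums and polarity counts from the other two common lexicon families.

**Prediction model.**  An ordinary-least-squares model of the openness
score on subject covariates and sentiment features, fitted after
excluding predictors with pairwise |Pearson r| > 0.60 (multicollinearity
filter) and stepwise selection (significance-threshold stepping by
default, bidirectional AIC optionally).  Split-sample evaluation (70/30)
reports RMSE, rank-based AUC, and sensitivity/specificity/accuracy at
the Youden-optimal operating point after median-split binarization;
external validation against an independent scale (e.g. a
disclosure-intention inventory) uses the Pearson correlation.

**Synthetic cohorts.**  Real transcripts of this kind cannot be shared,
so `simulate_cohort()` generates cohorts with known ground truth: the
openness outcome is linear in being single, academic education, the
narrative's fear count, informational support and net sentiment, and the
narrative text is constructed so that the pipeline recovers the planted
fear count and net sentiment *exactly* and the openness score up to
phrase quantization.  Every pipeline stage is tested against this
generator and against independent brute-force oracles.

## Worked example

```r
library(famcomm)

# score one narrative against the bundled 40-entry demonstration lexicon
lex <- demo_openness_lexicon()
s <- score_narrative(
  tokenize("We finally spoke openly, but my brother kept secret about the test."),
  lex)
s$matches
#>          ngram position score
#> 1 spoke openly        2     3
#> 2  kept secret        5    -3
s$score
#> [1] 0

# a full synthetic cohort through the whole pipeline
cohort <- simulate_cohort(sim_config(seed = 1))
res <- run_pipeline(cohort$narratives, cohort$subjects, split_seed = 2)
res$scores$summary$mean   # 29.54717
res$scores$summary$sd     # 19.14978
print(res$evaluation$fit)
#> Openness-of-communication prediction model
#>   n = 37 subjects; 19 candidates; 0 excluded as collinear; 5 selected
#>   criterion: stepwise p-value (enter 0.05 / remove 0.10)
#>   selected: informational_support, fear, net_sentiment, single, academic
#>   R-squared 0.9035 (adjusted 0.8879)
print(res$evaluation)
#> Split-sample evaluation (train fraction 0.7, seed 2)
#> Outcome binarized at training-median openness = 30
#> train (n=37): RMSE 6.077 | AUC 0.959 | sens 1.000 | spec 0.842 | acc 0.919
#> test (n=16): RMSE 11.209 | AUC 0.875 | sens 0.875 | spec 0.750 | acc 0.812
```

The training fit recovers the generator's planted model: all five true
predictors are selected, with estimates (e.g. support 12.45, fear 0.28,
net sentiment 0.18, single 15.7, academic −5.9) near the planted
coefficients, and test-set error is larger than training error as
expected.

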