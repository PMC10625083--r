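# chatmood

Analytics for depressive-mood discourse in open-domain chatbot conversation
logs.

People disclose sadness and depression to small-talk chatbots, and they do it
differently in different cultures and differently than on social media.
`chatmood` packages the full analysis pipeline for studying this: building a
keyword-based corpus of depressive/sad utterances from raw chat logs, scoring
psycholinguistic word categories and comparing Eastern vs Western users,
classifying utterances into eight depressive-discourse categories with a
semisupervised (pseudo-labeling) classifier, and comparing category
distributions across regions and platforms. Because real chatbot logs are
proprietary, the package ships a seeded synthetic corpus generator that
reproduces the statistical structure the analyses assume, so every stage is
testable and demonstrable offline.

It is aimed at computational social-science and digital-mental-health
researchers who want a reproducible, tested reference implementation of this
class of analysis.

## What it computes

**Corpus construction** (`read_corpus`, `filter_by_keywords`,
`sample_one_per_user`, `mask_pii`): keeps utterances containing any of nine
depressed/sad keyword phrases (substring matching, so the stem "depress"
hits "depressed"/"depression"), maps eight study countries to
Eastern/Western regions, samples one utterance per user, and masks digit
runs for privacy.

**Lexicon statistics** (`score_lexicon`, `welch_t`, `top_ngrams`,
`hourly_profile`): LIWC-style scoring — the score of utterance *u* for
category *c* with pattern set *L_c* is

    score(u, c) = 100 · #{tokens of u matching L_c} / #{tokens of u}

Group contrasts use Welch's unequal-variance t-test,

    t = (m₁ − m₂) / √(s₁²/n₁ + s₂²/n₂)

with Welch–Satterthwaite degrees of freedom, computable directly from
printed summary statistics. Diurnal profiles are per-region relative hourly
frequencies.

**Annotation** (`fleiss_kappa`, `consensus_filter`): Fleiss κ =
(P̄ − P̄ₑ)/(1 − P̄ₑ) for a fixed rater panel, and 3-of-4 modal-agreement
consensus filtering.

**Features and classification** (`build_vocab`, `pos_vector`, `embed_text`,
`fit_model`, `self_train`, `high_confidence_eval`): multi-hot bag-of-words
(min count 5), 46-tag PoS frequencies, and a deterministic hashing sentence
embedding, concatenated to |V| + 46 + E dimensions (6027 + 46 + 768 = 6841
under the reference configuration). Five classifier families (MLP, SVM,
random forest, naive Bayes, gradient boosted trees) expose calibrated
8-class probabilities. Self-training loops: train → pseudo-label pool items
with max probability > 0.9 → retrain from scratch → repeat; evaluation can
be restricted to high-confidence (≥ 0.9) predictions.

**Distribution comparison** (`category_shares`, `per_category_chi_square`,
`compare_to_reference`): exact category counts with half-up 2-dp percentage
shares, per-category 2×2 Pearson chi-square tests (df = 1, no continuity
correction) between regions, and side-by-side comparison against a packaged
Twitter reference distribution.

## Worked example

```r
library(chatmood)

cfg <- generator_config(n_users_per_region = 3000,
                        utterances_per_user = list(mean = 1, dispersion = 1),
                        seed = 2024)
corpus <- generate_corpus(cfg)
corpus
#> <synthetic_corpus> 6000 records, 60 annotated by 4 raters (seed 2024)

dep <- filter_by_keywords(corpus$records, keyword_set("depressed_sad"))
nrow(dep)   # 5427 of 6000 records carry a depressive keyword (rate 0.9)

hp <- hourly_profile(corpus$records)
c(hp$Eastern$peak_hour, hp$Western$peak_hour)
#> [1] 22 19
```

The generator plants evening chat peaks at 21h (Eastern) and 19h (Western);
with the default broad peak (mixture weight 0.6, spread 2 h) the empirical
modal hour can land on a neighbouring hour at this corpus size, as it does
for the Eastern group here.

```r
fleiss_kappa(corpus$annotations)$kappa
#> [1] 0.8369     # 60 items x 4 simulated raters at accuracy 0.95

lex <- demo_lexicons()
welch_t_from_samples(
  score_lexicon(dep$user_text[dep$region == "Eastern"], lex$present_focus),
  score_lexicon(dep$user_text[dep$region == "Western"], lex$present_focus))
#> Welch two-sample t test: t = 15.7216, df = 5210.7, p = 1.888e-54
#>   group1: mean 19.81 (SD 17), n = 2697
#>   group2: mean 13.16 (SD 14.01), n = 2730
```

The positive t reflects the generator's planted contrast: Eastern utterances
carry more present-focused feeling words, mirroring the published direction.

```r
top_ngrams(dep$user_text, n = 2, k = 5)
#>        ngram count proportion
#> 1     im sad  1323 0.09612730
#> 2  sad right   506 0.03676524
#> 3   feel sad   464 0.03371358
#> 4    i'm sad   462 0.03356826
#> 5 sad crying   442 0.03211509
```

A Welch t reconstructed purely from printed group summaries (negative
emotion words; means 29.68/29.17, SDs 20.76/20.40, n = 21,156 per group):

```r
welch_t(29.68, 20.76, 21156, 29.17, 20.40, 21156)
#> Welch two-sample t test: t = 2.5486, df = 42297.1, p = 0.01082
```

An end-to-end run (simulate → filter → lexicon stats → agreement → features
→ train → self-train → distributions → report) is one call:

```r
cfg <- read_run_config(system.file("extdata", "smoke_config.yaml",
                                   package = "chatmood"))
run_pipeline(cfg)   # writes corpus.jsonl, report.md, report.json, *.tsv
```

## Limitations

The synthetic generator produces template-bank text, not natural language;
classifier metrics on it are far higher than anything achievable on real
chat logs and demonstrate pipeline correctness, not expected real-world
performance. The packaged lexicons are small demonstration sets — full
psycholinguistic dictionaries are proprietary and must be supplied by the
user in the documented one-pattern-per-line format. See the methods
vignette (`vignettes/chatmood-methods.Rmd`) for the model, its assumptions,
and all numerical choices.
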