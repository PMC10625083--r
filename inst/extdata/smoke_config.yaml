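# Small end-to-end demonstration configuration. Sizes are deliberately tiny
# so a full pipeline run completes in well under two minutes; the labeled
# fraction is raised so every category is represented in the annotated
# subset at this scale.
seed: 42
model: mlp
threshold: 0.9
max_iters: 2
embedding_dim: 32
min_count: 2
vocab_scope: train
generator:
  n_users_per_region: 400
  utterances_per_user:
    mean: 1
    dispersion: 1
  labeled_fraction: 0.15
  rater_accuracy: 0.95
  n_raters: 4
  category_mixture:
    Eastern:
      dysfunctional_thoughts: 0.125
      lifestyle_challenges: 0.125
      social_struggles: 0.125
      hiding_behind_mask: 0.125
      apathy_sadness: 0.125
      suicidal_thoughts: 0.125
      seeking_relief: 0.125
      etc: 0.125
    Western:
      dysfunctional_thoughts: 0.125
      lifestyle_challenges: 0.125
      social_struggles: 0.125
      hiding_behind_mask: 0.125
      apathy_sadness: 0.125
      suicidal_thoughts: 0.125
      seeking_relief: 0.125
      etc: 0.125
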