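category	eastern_count	western_count	overall_count
dysfunctional_thoughts	8066	6319	14385
lifestyle_challenges	NA	NA	NA
social_struggles	6643	5062	11705
hiding_behind_mask	NA	NA	5870
apathy_sadness	47065	26980	74045
suicidal_thoughts	NA	NA	NA
seeking_relief	7659	3792	11451
etc	NA	NA	27101
total	92955	55635	148590
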