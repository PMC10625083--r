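{
  "platform": "Twitter (#MyDepressionLooksLike, qualitative content analysis)",
  "total": 1978,
  "categories": {
    "dysfunctional_thoughts": {
      "percent": 25.17,
      "numerator": 498,
      "provenance": "printed share for negative self-image tweets (498/1978, 25.17%)"
    },
    "social_struggles": {
      "percent": 21.89,
      "numerator": 433,
      "provenance": "printed share for relationship-struggle tweets (433/1978, 21.89%)"
    },
    "hiding_behind_mask": {
      "percent": 11.93,
      "numerator": 256,
      "provenance": "printed share 11.93% with printed fraction 256/1978; note 256/1978 = 12.94%, a discrepancy in the source. The printed percent is stored verbatim; this cell is excluded from numeric acceptance checks.",
      "discrepant": true
    },
    "apathy_sadness": {
      "percent": 7.53,
      "numerator": 149,
      "provenance": "printed share for apathy/sadness tweets (149/1978, 7.53%)"
    }
  }
}
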