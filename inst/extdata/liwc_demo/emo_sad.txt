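# demonstration lexicon: sadness
sad*
cry*
lonely
gloomy
grief*
depress*
miserable
tear*
empty
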