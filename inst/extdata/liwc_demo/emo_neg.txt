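# demonstration lexicon: negative emotion
sad*
depress*
hate*
hurt*
lonely
cry*
gloomy
distress*
awful
terrible
ashamed
anxious
angry
mad
scared
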