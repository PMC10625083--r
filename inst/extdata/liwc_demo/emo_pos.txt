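# demonstration lexicon: positive emotion
happy
joy*
love*
good
great
blessed
amazing
wonderful
excellent
delight*
proud
enjoy*
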