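# demonstration lexicon: physical / body
tired
pain
ache*
sick
body
head*
sleep*
stomach
eat*
appetite
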