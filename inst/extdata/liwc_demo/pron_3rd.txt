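# demonstration lexicon: third-person pronouns
he
she
it
they
him
her
them
his
hers
their
it's
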