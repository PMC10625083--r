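# demonstration lexicon: first-person pronouns
i
me
my
mine
myself
we
us
our
i'm
im
i've
i'll
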