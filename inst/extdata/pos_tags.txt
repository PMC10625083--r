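$
,
.
:
ADD
AFX
CC
CD
DT
EX
FW
HYPH
IN
JJ
JJR
JJS
LS
MD
NFP
NN
NNP
NNPS
NNS
PDT
POS
PRP
PRP$
RB
RBR
RBS
RP
SYM
TO
UH
VB
VBD
VBG
VBN
VBP
VBZ
WDT
WP
WP$
WRB
XX
_SP
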