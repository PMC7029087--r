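location,context,ecotype,n_fab,n_obt,intro_fab,intro_obt
BUR,sympatric,ME/FI,14,1,0,1
MOR,undetermined,,0,9,0,6
ABE,sympatric,FI,17,0,2,0
MURN,sympatric,FI,30,5,0,0
MURS,allopatric,FI,15,0,0,0
LANN,sympatric,ZS,19,20,10,0
LANS,allopatric,ZS,22,0,7,0
SEI,sympatric,ZS,25,24,12,0
ALDN,allopatric,,0,19,0,0
ALDS,sympatric,FI,12,6,11,0
BOR,sympatric,FI,27,15,9,5
TIR,sympatric,FI,39,1,4,0
CAG,sympatric,FI,22,19,4,9
RED,allopatric,,0,23,0,5
GUI,sympatric,FI,13,23,2,9
ALC,sympatric,FI,14,21,1,3
CAN,allopatric,FI,21,0,0,0
MAR,allopatric,ME,19,0,7,0
MOU,allopatric,ME,18,0,9,0
VIA,allopatric,,0,20,0,0
MOI,allopatric,,0,30,0,0
POV,allopatric,ME,21,0,0,0
MIN,sympatric,ME,34,32,0,0
AGU,allopatric,ME,19,0,0,0
CMU,sympatric,ME/FI,19,35,7,11
LEC,allopatric,ME,23,0,0,0
MAD,allopatric,ME,16,0,0,0
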