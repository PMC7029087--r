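group,label,n,clade1,clade2
location,ABE,1,0,1
location,LANN,1,0,1
location,SEI,2,2,0
location,CAG,1,0,1
location,GUI,1,1,0
location,MOU,2,0,2
location,MIN,2,1,1
location,CMU,47,9,38
class,F2,5,0,5
class,BCO,17,4,13
class,BCF,5,1,4
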