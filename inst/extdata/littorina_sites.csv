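location,code,context,fabalis,obtusata,ecotype,n_micros,n_mt,n_gm,lat,lon
Burela,BUR,sympatric,TRUE,TRUE,ME/FI,15,15,20,43.6667,-7.3564
Moras,MOR,undetermined,FALSE,TRUE,,9,9,0,43.7189,-7.4736
Abelleira,ABE,sympatric,TRUE,TRUE,FI,24,18,31,42.7981,-9.0250
Muros North,MURN,sympatric,TRUE,TRUE,FI,40,37,14,42.7736,-9.0517
Muros South,MURS,allopatric,TRUE,FALSE,FI,24,13,19,42.7428,-8.9814
Lanzada North,LANN,sympatric,TRUE,TRUE,ZS,44,39,30,42.4644,-8.8672
Lanzada South,LANS,allopatric,TRUE,FALSE,ZS,23,22,34,42.4606,-8.8719
Seixinos,SEI,sympatric,TRUE,TRUE,ZS,77,51,38,42.4578,-8.8231
Aldan North,ALDN,allopatric,FALSE,TRUE,,40,20,23,42.2797,-8.8203
Aldan South,ALDS,sympatric,TRUE,TRUE,FI,20,18,8,42.2767,-8.8247
Borna,BOR,sympatric,TRUE,TRUE,FI,42,42,24,42.2808,-8.6969
Tiran,TIR,sympatric,TRUE,TRUE,FI,49,40,36,42.2636,-8.7544
Cangas,CAG,sympatric,TRUE,TRUE,FI,55,42,49,42.2558,-8.7878
Redondela,RED,allopatric,FALSE,TRUE,,40,23,36,42.2875,-8.6228
La Guia,GUI,sympatric,TRUE,TRUE,FI,47,37,32,42.2586,-8.7036
Alcabre,ALC,sympatric,TRUE,TRUE,FI,42,35,29,42.2236,-8.7658
Canido,CAN,allopatric,TRUE,FALSE,FI,24,21,34,42.1922,-8.8053
As Marinas,MAR,allopatric,TRUE,FALSE,ME,24,19,0,42.1003,-8.8953
Mougas,MOU,allopatric,TRUE,FALSE,ME,24,20,0,42.0608,-8.8908
Viana do Castelo,VIA,allopatric,FALSE,TRUE,,39,20,36,41.6958,-8.8506
Rio de Moinhos,MOI,allopatric,FALSE,TRUE,,35,30,36,41.5667,-8.7972
Povoa de Varzim,POV,allopatric,TRUE,FALSE,ME,23,21,28,41.3847,-8.7747
Mindelo,MIN,sympatric,TRUE,TRUE,ME,70,68,47,41.3100,-8.7425
Agudela,AGU,allopatric,TRUE,FALSE,ME,32,19,26,41.2428,-8.7289
Cabo do Mundo,CMU,sympatric,TRUE,TRUE,ME/FI,111,101,39,41.2258,-8.7175
Leca da Palmeira,LEC,allopatric,TRUE,FALSE,ME,46,23,33,41.1983,-8.7119
Madalena,MAD,allopatric,TRUE,FALSE,ME,40,16,0,41.1022,-8.6628
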