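gene,snp_id,genotype_labels,n_1,n_2,n_3
ABCB1,rs3789243,AA/AG/GG,14,50,39
ABCB1,rs1128503,AA/AG/GG,42,51,10
ABCC2,rs2273697,GG/GA/AA,88,14,1
CYP1A1,rs2606345,CC/CA/AA,96,7,0
CYP2C9,rs1057910,AA/AC/CC,96,6,1
LEPR,rs1137101,AA/AG/GG,2,19,82
MTHFR,rs1801133,GG/GA/AA,51,35,17
MTHFR,rs1801131,TT/TG/GG,67,31,5
SCN1A,rs6732655,AA/AT/TT,4,97,2
SCN1A,rs6730344,CC/CA/AA,74,26,3
SCN1A,rs10167228,TT/TA/AA,1,17,85
SCN1A,rs3812718,CC/CT/TT,17,47,39
SCN1A,rs2298771,CC/CT/TT,1,18,84
SCN2A,rs2304016,AA/AG/GG,82,20,1
SCN2A,rs17183814,GG/GA/AA,73,28,2
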