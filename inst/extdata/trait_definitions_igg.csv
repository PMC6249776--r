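panel,trait,peak,weight
igg,G0,IGP1,1
igg,G0,IGP2,1
igg,G0,IGP3,1
igg,G0,IGP4,1
igg,G0,IGP5,1
igg,G0,IGP6,1
igg,G1,IGP7,1
igg,G1,IGP8,1
igg,G1,IGP9,1
igg,G1,IGP10,1
igg,G1,IGP11,1
igg,G1,IGP16,1
igg,G2,IGP12,1
igg,G2,IGP13,1
igg,G2,IGP14,1
igg,G2,IGP15,1
igg,G2,IGP17,1
igg,G2,IGP18,1
igg,G2,IGP19,1
igg,G2,IGP21,1
igg,G2,IGP22,1
igg,G2,IGP23,1
igg,G2,IGP24,1
igg,S0,IGP1,1
igg,S0,IGP2,1
igg,S0,IGP3,1
igg,S0,IGP4,1
igg,S0,IGP5,1
igg,S0,IGP6,1
igg,S0,IGP7,1
igg,S0,IGP8,1
igg,S0,IGP9,1
igg,S0,IGP10,1
igg,S0,IGP11,1
igg,S0,IGP12,1
igg,S0,IGP13,1
igg,S0,IGP14,1
igg,S0,IGP15,1
igg,S1,IGP16,1
igg,S1,IGP17,1
igg,S1,IGP18,1
igg,S1,IGP19,1
igg,S2,IGP21,1
igg,S2,IGP22,1
igg,S2,IGP23,1
igg,S2,IGP24,1
igg,Bisecting,IGP3,1
igg,Bisecting,IGP6,1
igg,Bisecting,IGP10,1
igg,Bisecting,IGP11,1
igg,Bisecting,IGP13,1
igg,Bisecting,IGP15,1
igg,Bisecting,IGP19,1
igg,Bisecting,IGP22,1
igg,Bisecting,IGP24,1
igg,OligoMan,IGP5,1
igg,CoreF,IGP1,1
igg,CoreF,IGP4,1
igg,CoreF,IGP6,1
igg,CoreF,IGP8,1
igg,CoreF,IGP9,1
igg,CoreF,IGP10,1
igg,CoreF,IGP11,1
igg,CoreF,IGP14,1
igg,CoreF,IGP15,1
igg,CoreF,IGP16,1
igg,CoreF,IGP18,1
igg,CoreF,IGP19,1
igg,CoreF,IGP23,1
igg,CoreF,IGP24,1
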