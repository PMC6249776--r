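panel,trait,peak,weight
plasma,LB,GP1,1
plasma,LB,GP3,1
plasma,LB,GP4,1
plasma,LB,GP5,1
plasma,LB,GP6,1
plasma,LB,GP8,1
plasma,LB,GP9,1
plasma,LB,GP10,1
plasma,LB,GP11,1
plasma,LB,GP12,1
plasma,LB,GP13,1
plasma,LB,GP14,1
plasma,LB,GP15,1
plasma,LB,GP16,1
plasma,LB,GP17,1
plasma,LB,GP18,1
plasma,LB,GP20,1
plasma,LB,GP21,1
plasma,LB,GP22,1
plasma,LB,GP23,1
plasma,LB,GP2,0.5
plasma,HB,GP24,1
plasma,HB,GP25,1
plasma,HB,GP26,1
plasma,HB,GP27,1
plasma,HB,GP28,1
plasma,HB,GP29,1
plasma,HB,GP30,1
plasma,HB,GP31,1
plasma,HB,GP32,1
plasma,HB,GP33,1
plasma,HB,GP34,1
plasma,HB,GP35,1
plasma,HB,GP36,1
plasma,HB,GP37,1
plasma,HB,GP38,1
plasma,HB,GP39,1
plasma,G0,GP1,1
plasma,G0,GP2,0.5
plasma,G1,GP3,1
plasma,G1,GP4,1
plasma,G1,GP5,1
plasma,G1,GP6,1
plasma,G1,GP12,1
plasma,G1,GP13,1
plasma,G2,GP8,1
plasma,G2,GP9,1
plasma,G2,GP10,1
plasma,G2,GP11,1
plasma,G2,GP14,1
plasma,G2,GP15,1
plasma,G2,GP16,1
plasma,G2,GP17,1
plasma,G2,GP18,1
plasma,G2,GP20,1
plasma,G2,GP21,1
plasma,G2,GP22,1
plasma,G2,GP23,1
plasma,G3,GP24,1
plasma,G3,GP25,1
plasma,G3,GP26,1
plasma,G3,GP27,1
plasma,G3,GP28,1
plasma,G3,GP29,1
plasma,G3,GP30,1
plasma,G3,GP31,1
plasma,G3,GP32,1
plasma,G3,GP35,1
plasma,G4,GP33,1
plasma,G4,GP34,1
plasma,G4,GP36,1
plasma,G4,GP37,1
plasma,G4,GP38,1
plasma,G4,GP39,1
plasma,S0,GP1,1
plasma,S0,GP3,1
plasma,S0,GP4,1
plasma,S0,GP5,1
plasma,S0,GP6,1
plasma,S0,GP8,1
plasma,S0,GP9,1
plasma,S0,GP10,1
plasma,S0,GP11,1
plasma,S0,GP2,0.5
plasma,S1,GP12,1
plasma,S1,GP13,1
plasma,S1,GP14,1
plasma,S1,GP15,1
plasma,S1,GP16,1
plasma,S1,GP17,1
plasma,S2,GP18,1
plasma,S2,GP20,1
plasma,S2,GP21,1
plasma,S2,GP22,1
plasma,S2,GP23,1
plasma,S2,GP24,1
plasma,S2,GP25,1
plasma,S2,GP26,1
plasma,S3,GP27,1
plasma,S3,GP28,1
plasma,S3,GP29,1
plasma,S3,GP30,1
plasma,S3,GP31,1
plasma,S3,GP32,1
plasma,S3,GP33,1
plasma,S3,GP34,1
plasma,S3,GP35,1
plasma,S4,GP36,1
plasma,S4,GP37,1
plasma,S4,GP38,1
plasma,S4,GP39,1
plasma,Bisecting,GP3,1
plasma,Bisecting,GP6,1
plasma,Bisecting,GP9,1
plasma,Bisecting,GP11,1
plasma,Bisecting,GP12,1
plasma,Bisecting,GP15,1
plasma,Bisecting,GP17,1
plasma,Bisecting,GP21,1
plasma,Bisecting,GP23,1
plasma,Bisecting,GP2,0.5
plasma,OligoMan,GP7,1
plasma,OligoMan,GP19,1
plasma,OligoMan,GP2,0.5
plasma,CoreF,GP1,1
plasma,CoreF,GP4,1
plasma,CoreF,GP5,1
plasma,CoreF,GP6,1
plasma,CoreF,GP10,1
plasma,CoreF,GP11,1
plasma,CoreF,GP13,1
plasma,CoreF,GP16,1
plasma,CoreF,GP17,1
plasma,CoreF,GP22,1
plasma,CoreF,GP23,1
plasma,CoreF,GP29,1
plasma,CoreF,GP31,1
plasma,CoreF,GP2,0.5
plasma,AntF,GP32,1
plasma,AntF,GP35,1
plasma,AntF,GP39,1
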