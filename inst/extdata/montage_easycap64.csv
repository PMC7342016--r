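channel,group,anterior,posterior
Fp1,Fp,TRUE,FALSE
Fpz,Fp,TRUE,FALSE
Fp2,Fp,TRUE,FALSE
AF7,AF,TRUE,FALSE
AF3,AF,TRUE,FALSE
AF4,AF,TRUE,FALSE
AF8,AF,TRUE,FALSE
F7,F,TRUE,FALSE
F5,F,TRUE,FALSE
F3,F,TRUE,FALSE
F1,F,TRUE,FALSE
F2,F,TRUE,FALSE
F4,F,TRUE,FALSE
F6,F,TRUE,FALSE
F8,F,TRUE,FALSE
FT9,FT,TRUE,FALSE
FT7,FT,TRUE,FALSE
FT8,FT,TRUE,FALSE
FT10,FT,TRUE,FALSE
FC5,FC,TRUE,FALSE
FC3,FC,TRUE,FALSE
FC1,FC,TRUE,FALSE
FCz,FC,TRUE,FALSE
FC2,FC,TRUE,FALSE
FC4,FC,TRUE,FALSE
FC6,FC,TRUE,FALSE
T7,T,TRUE,TRUE
T8,T,TRUE,TRUE
C5,C,TRUE,TRUE
C3,C,TRUE,TRUE
C1,C,TRUE,TRUE
Cz,C,TRUE,TRUE
C2,C,TRUE,TRUE
C4,C,TRUE,TRUE
C6,C,TRUE,TRUE
TP9,TP,FALSE,TRUE
TP7,TP,FALSE,TRUE
TP8,TP,FALSE,TRUE
TP10,TP,FALSE,TRUE
CP5,CP,FALSE,TRUE
CP3,CP,FALSE,TRUE
CP1,CP,FALSE,TRUE
CPz,CP,FALSE,TRUE
CP2,CP,FALSE,TRUE
CP4,CP,FALSE,TRUE
CP6,CP,FALSE,TRUE
P7,P,FALSE,TRUE
P5,P,FALSE,TRUE
P3,P,FALSE,TRUE
P1,P,FALSE,TRUE
Pz,P,FALSE,TRUE
P2,P,FALSE,TRUE
P4,P,FALSE,TRUE
P6,P,FALSE,TRUE
P8,P,FALSE,TRUE
PO7,PO,FALSE,TRUE
PO3,PO,FALSE,TRUE
POz,PO,FALSE,TRUE
PO4,PO,FALSE,TRUE
PO8,PO,FALSE,TRUE
O1,O,FALSE,TRUE
Oz,O,FALSE,TRUE
O2,O,FALSE,TRUE
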