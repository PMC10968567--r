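channel,row,col
FP1,0,3
FPZ,0,4
FP2,0,5
F7,2,0
F3,2,2
FZ,2,4
F4,2,6
F8,2,8
FC5,3,1
FC1,3,3
FC2,3,5
FC6,3,7
M1,4,0
T7,4,1
C3,4,2
CZ,4,4
C4,4,6
T8,4,7
M2,4,8
CP5,5,1
CP1,5,3
CP2,5,5
CP6,5,7
P7,6,0
P3,6,2
PZ,6,4
P4,6,6
P8,6,8
POZ,7,4
O1,8,3
OZ,8,4
O2,8,5
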