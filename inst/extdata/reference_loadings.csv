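index,PC1,PC2,SPC1,SPC2
R,0.173673,-0.17527,0.190384,0
G,0.193318,-0.13006,0.25154,0
B,-0.04634,-0.34902,0.029027,0
NR,0.112447,0.184999,0,0
NG,0.195725,0.118161,0,0
NB,-0.18671,-0.1504,0,0
GB,0.107347,0.289417,0.001645,0
RB,0.098209,0.290244,0.001023,0
GR,0.184904,0.037012,0.000741,0
BI,0.174901,-0.19118,0.172234,0
BIM,0.162807,-0.22338,0.012636,0
SCI,-0.18633,-0.02744,0,0
GLI,0.198202,0.105196,0.001438,0
HI,0.009223,0.039836,-0.00091,0
NGRDI,0.186327,0.027439,0,0
NDGBI,0.187861,0.155,0.001253,0
NDRBI,0.170895,0.194543,0.000646,0
I,0.161255,-0.22798,0.478908,0
S,0.186705,0.150404,0.000897,0
VARI,0.192465,0.000261,0,0
HUE,-0.19007,-0.0248,-0.00694,0
HUE2,-0.16947,-0.01249,-0.00573,0
BGI,-0.19762,-0.09568,-0.00164,0
L,0.179046,-0.17924,0.457194,0
GRAY,0.184074,-0.16516,0.207812,0
GLAI,0.192465,0.000261,0.014478,0
CI,0.182407,0.13823,0.001129,0
SHP,-0.01298,-0.01486,-0.00018,-1
RI,-0.1057,0.288167,0,0
RminB,0.194727,0.040558,0.160705,0
RplusB,0.097349,-0.29776,0.208727,0
RplusG,0.183643,-0.15131,0.436911,0
RminG,-0.18022,-0.00587,-0.05907,0
GminB,0.202835,0.031916,0.224126,0
BplusG,0.141039,-0.25804,0.27192,0
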