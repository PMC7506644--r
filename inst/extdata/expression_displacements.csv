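expression,landmark,dx,dy,dz
SU,1,0,6,0
SU,2,0,8,0
SU,3,0,9,0
SU,4,0,9,0
SU,5,0,8,0
SU,6,0,6,0
SU,16,2,-6,0
SU,17,0,-4,0
SU,18,-2,-6,0
SU,19,0,-2,0
SU,20,0,-14,0
SU,21,0,-18,0
SU,22,0,-24,-2
SA,2,0,1,0
SA,3,0,5,0
SA,4,0,5,0
SA,5,0,1,0
SA,16,0,-4,0
SA,18,0,-4,0
SA,21,0,-2,0
SA,22,0,2,0
HA,16,-7,5,-3
HA,17,0,2,0
HA,18,7,5,-3
HA,19,0,1,0
HA,20,0,-4,0
HA,21,0,-6,0
HA,22,0,-6,0
FE,1,2,5,0
FE,2,1,6,0
FE,3,3,7,0
FE,4,-3,7,0
FE,5,-1,6,0
FE,6,-2,5,0
FE,16,-3,-2,0
FE,18,3,-2,0
FE,20,0,-5,0
FE,21,0,-7,0
FE,22,0,-8,0
DI,11,0,-2,0
DI,12,0,-2,0
DI,13,0,3,0
DI,15,0,2,0
DI,16,0,4,0
DI,17,-2,6,2
DI,18,0,1,0
DI,19,-2,4,0
AN,2,1,-3,0
AN,3,4,-6,0
AN,4,-4,-6,0
AN,5,-1,-3,0
AN,16,2,0,0
AN,17,0,-1,0
AN,18,-2,0,0
AN,19,0,-1,0
AN,20,0,1,0
AN,21,0,1,0
AN,22,0,1,0
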