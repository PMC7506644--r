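index,name,x,y,z
1,Outer left eyebrow,-55,42,0
2,Middle left eyebrow,-35,48,8
3,Inner left eyebrow,-16,45,10
4,Inner right eyebrow,16,45,10
5,Middle right eyebrow,35,48,8
6,Outer right eyebrow,55,42,0
7,Outer left eye corner,-45,30,0
8,Inner left eye corner,-16.5,30,5
9,Inner right eye corner,16.5,30,5
10,Outer right eye corner,45,30,0
11,Nose saddle left,-10,34,8
12,Nose saddle right,10,34,8
13,Left nose peak,-17,-2,12
14,Nose tip,0,0,22
15,Right nose peak,17,-2,12
16,Left mouth corner,-26,-25,6
17,Upper lip outer middle,0,-18,12
18,Right mouth corner,26,-25,6
19,Upper lip inner middle,0,-22,10
20,Lower lip inner middle,0,-26,10
21,Lower lip outer middle,0,-32,11
22,Chin middle,0,-60,8
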