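canonical_index,method,source1,source2
1,copy,eyebrow_left_1,
2,copy,eyebrow_left_3,
3,copy,eyebrow_left_5,
4,copy,eyebrow_right_1,
5,copy,eyebrow_right_3,
6,copy,eyebrow_right_5,
7,copy,eye_left_1,
8,copy,eye_left_4,
9,copy,eye_right_1,
10,copy,eye_right_4,
11,midpoint,eye_left_4,nose_bridge_1
12,midpoint,eye_right_1,nose_bridge_1
13,copy,nose_lower_1,
14,copy,nose_bridge_4,
15,copy,nose_lower_5,
16,copy,mouth_outer_1,
17,copy,mouth_outer_4,
18,copy,mouth_outer_7,
19,copy,mouth_inner_3,
20,copy,mouth_inner_7,
21,copy,mouth_outer_10,
22,midpoint,mouth_outer_9,mouth_outer_11
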