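athlete,stage1_8kmh,stage2_9kmh,stage3_10kmh,stage4_11kmh,stage5_12kmh
1,85.05,79.20,84.24,86.75,80.63
2,83.16,83.19,83.63,82.68,85.77
3,86.40,86.67,86.52,87.79,87.15
4,86.13,85.57,85.31,84.66,82.77
5,84.46,81.22,85.91,82.81,82.65
6,82.61,80.17,84.06,77.74,82.46
7,85.96,84.51,85.37,86.32,85.37
8,85.65,87.42,84.39,85.67,81.25
9,84.71,87.97,86.59,79.67,87.10
10,70.80,87.84,82.03,72.91,86.13
11,80.22,87.06,82.17,87.17,86.31
12,84.82,84.94,82.46,82.68,84.53
13,80.12,82.07,87.49,81.70,85.20
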