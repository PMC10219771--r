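athlete,alpha_pct,alpha_sd,experience
1,77.04,7.97,less_than_10y
2,70.44,6.07,less_than_10y
3,64.49,5.13,less_than_10y
4,79.53,7.53,less_than_10y
5,81.87,4.32,less_than_10y
6,72.56,6.26,less_than_10y
7,84.05,6.97,10_to_15y
8,83.29,6.53,10_to_15y
9,95.65,3.12,over_15y
10,88.79,4.28,over_15y
11,83.03,3.64,over_15y
12,85.73,4.95,over_15y
13,86.67,3.00,over_15y
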