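offset_weeks,probability
-17,0.0004
-16,0.0005
-15,0.0006
-14,0.0008
-13,0.0010
-12,0.0014
-11,0.0018
-10,0.0025
-9,0.0035
-8,0.0050
-7,0.0080
-6,0.0130
-5,0.0220
-4,0.0400
-3,0.0800
-2,0.1500
-1,0.2200
0,0.2400
1,0.1700
2,0.0350
3,0.0038
4,0.0005
5,0.0002
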