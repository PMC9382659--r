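# three-loop pattern: L1 crosses L2 and L3, L2 nested in L3
N 3
1	2	x
1	3	x
2	3	n
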