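leaf_order,npq_control,npq_uvb
2,0.49,0.40
3,0.39,0.45
4,0.65,0.47
5,0.45,0.47
6,0.43,0.55
7,0.45,0.71
8,0.49,0.57
9,0.49,0.85
10,0.57,1.27
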