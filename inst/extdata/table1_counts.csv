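category,labeled,unlabeled
1,8,781
2,9,2937
3,12,183
4,47,688
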