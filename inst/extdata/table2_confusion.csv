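true,pred_1,pred_2,pred_3,pred_4
1,29,1,4,2
2,1,63,5,0
3,1,2,5,1
4,0,0,3,3
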