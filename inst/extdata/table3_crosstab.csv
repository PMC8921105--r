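isup,mG1,mG2,mG3
1,17,20,3
2,10,24,13
3,4,20,26
4,0,14,36
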