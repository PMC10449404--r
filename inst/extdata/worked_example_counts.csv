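r,low,high
0,138,5
1,440,415
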