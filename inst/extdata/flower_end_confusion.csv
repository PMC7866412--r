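Turning,Pink,Light Red,Red,Deep Red
0.8,0.1,0.03,0,0
0.15,0.8,0.06,0,0
0.05,0.1,0.82,0.1,0.05
0,0,0.06,0.8,0.1
0,0,0.03,0.1,0.85
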