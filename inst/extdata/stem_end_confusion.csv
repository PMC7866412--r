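Turning,Pink,Light Red,Red,Deep Red
0.9,0.04,0,0,0
0.1,0.92,0.05,0,0
0,0.04,0.9,0.02,0.02
0,0,0.05,0.9,0.08
0,0,0,0.08,0.9
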