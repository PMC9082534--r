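id,lp,risk
w01,-0.0006,0.1998929161
w02,0.7494,0.3763160629
w03,-0.0006,0.1998929161
w04,0.5994,0.3339231181
w05,0.3494,0.2712800928
w06,0.5994,0.3339231181
w07,0.1994,0.2384387444
w08,0.9494,0.4382162835
w09,0.1994,0.2384387444
w10,0.7994,0.3912315072
w11,0.5494,0.3205911824
w12,0.7994,0.3912315072
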