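tbr,intercept,slope,r_squared
infinity,99.8,-16.1,0.96
10:1,99.8,-16.1,0.97
5:1,103.0,-15.6,0.98
pooled,100.9,-16.0,0.95
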