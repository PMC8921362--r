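kind,iterations,tbr,mean,sd
cortex-only,36,infinity,48.4,8.3
cortex-only,36,10:1,48.0,7.2
cortex-only,36,5:1,52.5,6.0
cortex-only,72,infinity,49.8,7.9
cortex-only,72,10:1,49.7,7.4
cortex-only,72,5:1,54.2,6.3
whole-parenchyma,36,infinity,76.9,1.2
whole-parenchyma,36,10:1,76.3,1.5
whole-parenchyma,36,5:1,79.7,1.2
whole-parenchyma,72,infinity,77.1,1.4
whole-parenchyma,72,10:1,77.5,1.4
whole-parenchyma,72,5:1,81.1,1.2
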