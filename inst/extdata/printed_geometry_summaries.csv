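kind,quantity,mean,sd
cortex-only,volume_cm3,123.3,26.8
cortex-only,surface_cm2,370.7,48.4
cortex-only,sav_cm1,3.1,0.4
whole-parenchyma,volume_cm3,171.2,10.2
whole-parenchyma,surface_cm2,243.8,15.5
whole-parenchyma,sav_cm1,1.4,0.0
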