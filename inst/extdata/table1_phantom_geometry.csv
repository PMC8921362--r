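id,kind,volume_cm3,surface_cm2,sav_cm1
Pat1L,cortex-only,135.5,367.3,2.7
Pat1R,cortex-only,129.3,410.3,3.2
Pat2L,cortex-only,124.4,398.6,3.2
Pat2R,cortex-only,94.8,365.9,3.9
Pat3L,cortex-only,70.4,244.4,3.5
Pat3R,cortex-only,156.3,376.6,2.4
Pat4L,cortex-only,162.0,419.5,2.6
Pat5R,cortex-only,113.8,388.6,3.4
Pat6L,cortex-only,123.0,365.2,3.0
Pat7L,whole-parenchyma,160.1,230.9,1.4
Pat7R,whole-parenchyma,167.9,246.6,1.5
Pat8L,whole-parenchyma,182.0,256.8,1.4
Pat8R,whole-parenchyma,181.8,257.7,1.4
Pat9L,whole-parenchyma,167.2,229.8,1.4
Pat9R,whole-parenchyma,187.9,264.1,1.4
Pat10L,whole-parenchyma,173.1,243.7,1.4
Pat10R,whole-parenchyma,171.1,260.1,1.5
Pat11L,whole-parenchyma,168.6,234.9,1.4
Pat11R,whole-parenchyma,151.9,213.8,1.4
Ellipsoid,ellipsoid,212.5,180.2,0.8
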