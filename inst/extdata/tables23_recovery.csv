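id,kind,inf_36,tbr10_36,tbr5_36,inf_72,tbr10_72,tbr5_72
Pat1L,cortex-only,56.1,54.2,57.4,57.2,56.3,59.5
Pat1R,cortex-only,60.8,58.8,61.9,60.6,60.9,64.2
Pat2L,cortex-only,45.7,45.0,49.6,47.1,46.7,51.3
Pat2R,cortex-only,43.5,43.9,47.7,46.3,45.8,50.0
Pat3L,cortex-only,37.9,37.4,42.4,38.8,38.8,43.6
Pat3R,cortex-only,36.3,39.1,48.4,38.0,40.2,49.5
Pat4L,cortex-only,53.8,52.5,57.1,54.3,53.9,59.0
Pat5R,cortex-only,51.8,52.0,55.1,54.2,53.0,56.6
Pat6L,cortex-only,49.8,49.8,52.9,51.3,51.5,54.5
Pat7L,whole-parenchyma,75.3,74.5,78.5,75.2,75.5,80.3
Pat7R,whole-parenchyma,76.0,75.3,80.5,76.9,76.6,82.3
Pat8L,whole-parenchyma,77.3,75.9,78.3,77.5,77.6,80.4
Pat8R,whole-parenchyma,76.8,76.6,80.0,76.9,78.1,80.1
Pat9L,whole-parenchyma,77.9,74.8,79.4,78.9,76.0,80.8
Pat9R,whole-parenchyma,74.8,75.4,78.7,74.5,76.4,79.8
Pat10L,whole-parenchyma,78.5,78.5,82.3,78.3,79.4,83.9
Pat10R,whole-parenchyma,77.1,76.0,79.5,77.8,76.9,81.0
Pat11L,whole-parenchyma,77.1,78.3,80.0,77.5,79.2,81.5
Pat11R,whole-parenchyma,77.7,77.9,79.8,78.1,78.9,80.9
Ellipsoid,ellipsoid,85.4,82.8,89.0,85.4,83.3,89.6
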