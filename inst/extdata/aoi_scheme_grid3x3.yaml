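# Example AOI geometry config: the default 3x3 grid over normalized
# coordinates, columns left/centre/right, rows top (distant) to bottom.
coordinate_space: "normalized [0,1] x [0,1]"
regions:
  - {aoi: A, xmin: 0.0000, xmax: 0.3333, ymin: 0.6667, ymax: 1.0000}
  - {aoi: D, xmin: 0.3333, xmax: 0.6667, ymin: 0.6667, ymax: 1.0000}
  - {aoi: G, xmin: 0.6667, xmax: 1.0000, ymin: 0.6667, ymax: 1.0000}
  - {aoi: B, xmin: 0.0000, xmax: 0.3333, ymin: 0.3333, ymax: 0.6667}
  - {aoi: E, xmin: 0.3333, xmax: 0.6667, ymin: 0.3333, ymax: 0.6667}
  - {aoi: H, xmin: 0.6667, xmax: 1.0000, ymin: 0.3333, ymax: 0.6667}
  - {aoi: C, xmin: 0.0000, xmax: 0.3333, ymin: 0.0000, ymax: 0.3333}
  - {aoi: F, xmin: 0.3333, xmax: 0.6667, ymin: 0.0000, ymax: 0.3333}
  - {aoi: I, xmin: 0.6667, xmax: 1.0000, ymin: 0.0000, ymax: 0.3333}
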