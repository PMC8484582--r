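# Commercial rectangular flow-channel registry (dimensions in mm).
ibidi_VI_0.4:
  height_mm: 0.4
  width_mm: 3.8
  length_mm: 17
ibidi_VI_0.5:
  height_mm: 0.54
  width_mm: 3.8
  length_mm: 17
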