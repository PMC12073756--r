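# Reduced-geometry configuration for quick demos and smoke runs.
scene:
  rows: 64
  cols: 80
  marginRows: 8
scan:
  nFrames: 150
training:
  epochs: 10
  batchSize: 128
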