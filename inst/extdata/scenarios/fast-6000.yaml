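# Single-shot syringe injection: 500 uL at 6 mL/min (5 s), one frame per second.
protocol:
  flow_rate: 6000
  total_volume: 500
  mode: single_shot
  needle_tip: [600, 800]
  frame_interval: 1
tissue:
  epsilon: 1.0
  anisotropy: 0.6        # strongly horizontal spreading at fast injection
  lag_volume: 100
  mu_abs: 1.0
geometry:
  dims: [1200, 1600]
  pixel_size: 9
frames:
  start: 0
  end: 30
  interval: 1
seed: 20170831
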