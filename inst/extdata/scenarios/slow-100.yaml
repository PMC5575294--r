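# Continuous pump infusion: 500 uL at 100 uL/min (5 min), one frame per 10 s.
protocol:
  flow_rate: 100
  total_volume: 500
  mode: continuous
  needle_tip: [600, 800]
  frame_interval: 10
tissue:
  epsilon: 1.0
  anisotropy: 1.0
  lag_volume: 100        # onset at 60 s
  mu_abs: 1.0
geometry:
  dims: [1200, 1600]
  pixel_size: 9
frames:
  start: 0
  end: 360
  interval: 10
seed: 20170830
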