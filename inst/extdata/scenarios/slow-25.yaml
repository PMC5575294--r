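# Continuous pump infusion: 500 uL at 25 uL/min (20 min), one frame per minute.
protocol:
  flow_rate: 25          # uL/min
  total_volume: 500      # uL
  mode: continuous
  needle_tip: [600, 800] # row, col
  frame_interval: 60     # s
tissue:
  epsilon: 1.0
  anisotropy: 1.0
  lag_volume: 100        # uL dead volume -> onset at 240 s
  mu_abs: 1.0            # 1/mm
geometry:
  dims: [1200, 1600]     # 10.8 x 14.4 mm at 9 um
  pixel_size: 9          # um
frames:
  start: 0
  end: 1500
  interval: 60
seed: 20170829
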