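# Example proxy configuration for a synthetic black-carbon data set.
output: BC
candidates: [X1, X2, X3, X4, X5, X6, X7, X8, X9, X10, Temp, WD]
transforms:
  BC: log
  X1: log
  X2: log
  X3: log
  X4: log
  X5: log
  X6: log
  X7: log
  X8: log
  X9: log
  X10: log
  Temp: identity
  WD: wind_direction
season_temp: Temp
thresholds:
  r_min: 0.1
  vif_max: 5
  alpha: 0.05
  max_inputs: 3
  bootstrap_reps: 5
  bootstrap_fraction: 0.8
  min_n: 30
holidays: finland_2017_2018
seed: 0
tz_label: UTC+2
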