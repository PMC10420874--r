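# Desk-scale perpendicular pulling experiment (trend-level stand-in for the
# full 80x80x600 rc^3 geometry). All fields mirror scenario_config().
box: [14.0, 14.0, 60.0]
N: 50
direction: z
force: 3.0
aPH: -5.0
replicas: 3
n_equil: 500
stride: 100
max_time: 50.0
rod_threshold: 0.65
coil_threshold: 0.3
termination: transition
sweep:
  forces: [2.0, 2.5, 3.0]
  aPH: [-5.0]
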