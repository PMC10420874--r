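# Desk-scale parallel pulling experiment (trend-level stand-in for the full
# 800x60x40 rc^3 geometry).
box: [40.0, 20.0, 20.0]
N: 50
direction: x
force: 2.0
aPH: -20.0
replicas: 3
n_equil: 500
stride: 100
max_time: 200.0
termination: exit
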