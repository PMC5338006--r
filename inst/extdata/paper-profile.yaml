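# Full-scale profile: 20,000 steps of 30 simulated minutes on a 200 x 200 um
# domain. Runs take many hours on one CPU; opt-in.
profile: paper
steps: 20000
seed: 42
nStem: 32
humidity: 100
outputEvery: 100
membrane:
  mode: undulated
  meanHeight: 0
  amplitude: 20
  period: 100
  Lx: 200
  Ly: 200
behaviour:
  stemCycle: [280, 360]
  taCycle: [140, 180]
  sgMaturation: 160
  adhesionPeak: 260
  adhesionDecay: 0.0055
  lowWaterPersist: 60
transport:
  Dw: 2.5e-05
  Dca: 2.0e-05
  dermisRateCalcium: 0.007
  tewlCoeff: 0.0035
  bindRate: 0.007
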