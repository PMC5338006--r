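# Reduced-scale profile: one rete-ridge period, desk-scale runtimes.
# Values shown here repeat the package defaults; edit to override.
profile: reduced
steps: 1200
seed: 42
nStem: 8
humidity: 100
membrane:
  mode: undulated
  meanHeight: 0
  amplitude: 10
  period: 60
  Lx: 60
  Ly: 60
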