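# Causal-inverse demo: variable (explorative) motor code.
# Expected outcome: mirroring offset near the loop delay tau = 40 ms.
seed: 7
code:
  kind: variable
  nNeurons: 4
  t0: 10
  dt: 1
  renditionLen: 4000
  renditionsPerEpoch: 15
map:
  nSensory: 4
  tauM: 25
  tauA: 15
  conditionCap: 5
trace:
  kind: exponential
  decayTime: 80
learning:
  nEpochs: 25
  rateScale: 1.0
mirroring:
  maxLag: 100
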