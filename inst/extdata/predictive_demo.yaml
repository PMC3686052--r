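# Predictive-inverse demo: stereotyped traveling-pulse code.
# The eligibility here decays fast relative to the inter-burst lag
# (decay 20 ms < lag / ln 2), the regime in which the mirroring offset
# collapses to (near) zero; shallower traces move the peak out to the
# inter-burst lag (see the methods vignette).
seed: 7
code:
  kind: stereotyped
  nNeurons: 4
  t0: 10
  dt: 1
  interBurstLag: 20
  cycles: 1
map:
  nSensory: 4
  tauM: 25
  tauA: 15
  conditionCap: 5
trace:
  kind: exponential
  decayTime: 20
learning:
  nEpochs: 400
  convergenceTol: 1.0e-7
  tailFrac: 0.05
mirroring:
  maxLag: 100
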