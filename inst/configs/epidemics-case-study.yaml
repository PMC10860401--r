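# End-to-end pipeline for the plant-epidemics case study: local
# collinearity table, risk/PLCI table and ARE table at the reference
# parameters, observing infected and total stems every other day on
# days 2-12 with 1.5%-of-time-mean Gaussian noise.
seed: 1
outdir: epidemics-output
model:
  name: epidemics
  variant: removal
protocol:
  times: [2, 4, 6, 8, 10, 12]
  observed: ["I", "N"]
  noise:
    I: {type: relative, value: 0.015}
    "N": {type: relative, value: 0.015}
analyses:
  simulate: true
  dataset: {}
  collinearity:
    min_size: 2
    scaling: global
  risk:
    parameters: [b, kappa, lambda0, mu, d]
    alpha: 0.95
  are:
    N: 100
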