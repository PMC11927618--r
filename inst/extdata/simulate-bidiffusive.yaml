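# Monte Carlo splitting estimate for a Maxwell-fluid tracer
task: simulate
model:
  type: bidiffusive
  B: 10
x0: 4.16
L: 20
n_steps: 20000
dt: 0.015
n_paths: 5000
seed: 1
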