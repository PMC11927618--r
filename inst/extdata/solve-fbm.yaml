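# Solve the two-target splitting problem for a superdiffusive walker
task: solve
model:
  type: powerlaw
  kappa: 1
  H: 0.6
x0: 0.208
L: 1
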