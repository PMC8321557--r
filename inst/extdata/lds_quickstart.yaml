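# Quick-start run configuration: 2-D linear dynamical system conditioned on
# the 1 Hz oscillation band. Reduced optimizer settings for a fast demo run;
# see the methods vignette for the benchmark-scale settings.
model: lds2d
property:
  statNames: [real_lambda1, imag_lambda1]
  mu: [0.0, 6.283185307179586]
  sigma2: [0.0625, 0.39478417604357434]
  innerTrials: 1
optimizer:
  imax: 200
  kmax: 6
  batchN: 200
init:
  sd: [4, 4, 4, 4]
  iters: 800
seed: 1
outDir: runs/lds-quickstart
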