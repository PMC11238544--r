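# Ten exploratory WTmetaD runs plus ten WTmetaD runs restrained to the
# transition region by a 2D harmonic potential.
outdir: mfi_doublewell2d_mixed
potential: {type: builtin, name: doublewell2d}
reference: {type: builtin, name: doublewell2d}
domain:
  bounds: [[-3.0, 3.0], [-3.0, 3.0]]
  nbins: [100, 100]
  periodic: [false, false]
langevin: {kT: 1.0, friction: 1.0, dt: 0.005, nsteps: 100000, sample_stride: 20, x0: random}
metad: {w0: 1.0, sigma: [0.15, 0.15], pace: 200, bias_factor: 15}
kde: {h: 0.1}
integrator: fd
runs:
  - {seed: 301}
  - {seed: 302}
  - {seed: 303}
  - {seed: 304}
  - {seed: 305}
  - {seed: 311, static_biases: [{type: harmonic, center: [0.1, 0.0], kappa: [2.0, 2.0]}]}
  - {seed: 312, static_biases: [{type: harmonic, center: [0.1, 0.0], kappa: [2.0, 2.0]}]}
  - {seed: 313, static_biases: [{type: harmonic, center: [-0.6, 0.4], kappa: [2.0, 2.0]}]}
  - {seed: 314, static_biases: [{type: harmonic, center: [0.8, -0.5], kappa: [2.0, 2.0]}]}
  - {seed: 315, static_biases: [{type: harmonic, center: [0.8, -0.5], kappa: [2.0, 2.0]}]}
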