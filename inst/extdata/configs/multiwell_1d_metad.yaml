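# Single well-tempered metadynamics run on the 1D multiwell profile.
outdir: mfi_multiwell1d
potential: {type: builtin, name: multiwell1d}
reference: {type: builtin, name: multiwell1d}
domain:
  bounds: [[-0.3, 1.3]]
  nbins: [200]
  periodic: [false]
langevin: {kT: 1.0, friction: 1.0, dt: 0.002, nsteps: 200000, sample_stride: 10, x0: random}
metad: {w0: 0.5, sigma: 0.04, pace: 200, bias_factor: 10}
kde: {h: 0.02}
integrator: fd
seeds: [101]
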