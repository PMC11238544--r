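# Twenty short randomly initialized WTmetaD runs on the 2D double well,
# merged into one surface.
outdir: mfi_doublewell2d
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
seeds: [201, 202, 203, 204, 205, 206, 207, 208, 209, 210,
        211, 212, 213, 214, 215, 216, 217, 218, 219, 220]
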