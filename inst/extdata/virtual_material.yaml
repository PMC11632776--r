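# Virtual-material pipeline configuration: one section per subcommand.
# Values override the package defaults (see ?run_virtual_material).
pipeline:
  thermal:
    tg: 400.0          # K, hinge of the synthetic cooling curve
    noise_sd: 0.0005   # cm^3/g
  hbond:
    n_bonds: 10000
    dt: 0.01           # ns
    k_break: 1.0       # 1/ns
    k_reform: 0.0
  mech:
    E_true: 3.0        # GPa
    nu_true: 0.3
    noise_sd: 0.05     # GPa
  freevol:
    n_atoms: 60
    radius: 0.15       # nm
  diffusion:
    D_true: 0.1        # nm^2/ns = 1.0e-6 cm^2/s
    n_particles: 100
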