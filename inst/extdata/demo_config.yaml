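# Demonstration configuration: a small solution-state ensemble with the
# per-helix nick kinks, mild breathing and noise, plus an ohmic swap
# ledger at the reference conductance. Omitted keys take the documented
# defaults of the corresponding parameter constructors.
seed: 1

bundle:
  n_helices: 6
  bp_per_duplex: 21
  nick_residue: 14
  loop_len: 4
  cholesterol_helices: [2, 4, 6]

distortions:
  axis_spacing_s: 21
  kink_per_helix: [40.0, 62.5, 50.8, 67.3, 62.5, 31.0]
  breathing_amplitude: 2
  breathing_period: 50
  fray_prob: 0.05
  noise_sigma: 0.8

ions:
  concentration: 1.0
  lumen_enhancement:
    Na: 0.19
    water: 1.8

ledger:
  conductance_G: 1.19

ensemble:
  n_replicas: 3
  n_frames: 20
  dt_ns: 1

analysis:
  bpb_cutoff: 8
  cluster_cutoff: 3
  density_frames: 20
  bootstrap_B: 500
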