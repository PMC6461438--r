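{
  "comment": "SYNTHETIC example Ising parameters for a 20-repeat consensus TALE array. These are round placeholder magnitudes of plausible sign and order only; the measured intrinsic/interfacial free energies are published elsewhere and are NOT reproduced here. kcal/mol.",
  "synthetic": true,
  "dg_intrinsic": [2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0,
                   2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0],
  "dg_interface": [-5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0,
                   -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0],
  "RT": 0.593
}
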