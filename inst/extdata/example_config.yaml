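# Example configuration: structure grammar and chromatogram simulation.
grammar:
  n_range: [3, 4, 5]
  acyl:
    carbons: [12, 14, 16, 18, 20, 22]
    double_bonds: [0, 1, 2, 3]
  allowed:
    R2: [H, Me]
    R3: [H, Ac, Cb]
    R4: [H, Cb]
    R5: [H, Ac]
    R6: [H, S, Fuc, MeFuc, FucS, Ac]
simulation:
  planted:
    - {structure: "LCO-IV(C16:0,S)", rt: 6.2}
    - {structure: "CO4", rt: 2.4}
  amplitude_range: [500, 2000]
  sigma: 0.05
  noise_sd: 5
  dropout: 0
  seed: 42
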