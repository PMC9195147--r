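# Demo configuration: regenerates the full synthetic study.
# Variant samples follow the report-table naming convention (D104G_90_*,
# Y123S_90_*, S161I_90_*): the variants are carried on the 90-210 fragment
# even where source sample tables list them under the 81-210 column; the
# naming inconsistency is documented, not resolved.
seed: 20260923
noise_sd: 0
melt:
  grid: {from: 20, to: 95, by: 0.5}
  samples:
    - {name: wt_81_none, fragment: 81-210, equivalents: none,
       transitions: [{tm: 65, dh: 300}]}
    - {name: wt_81_0.8, fragment: 81-210, equivalents: "0.8",
       partner: wt_81_none, transitions: [{tm: 65, dh: 300}]}
    - {name: wt_90_none, fragment: 90-210, equivalents: none,
       transitions: [{tm: 66, dh: 300}]}
    - {name: wt_90_0.8, fragment: 90-210, equivalents: "0.8",
       partner: wt_90_none, transitions: [{tm: 60, dh: 300}]}
    - {name: D104G_90_none, fragment: 90-210, equivalents: none,
       transitions: [{tm: 68, dh: 300}]}
    - {name: D104G_90_0.8, fragment: 90-210, equivalents: "0.8",
       partner: D104G_90_none, transitions: [{tm: 63, dh: 300}]}
    - {name: Y123S_90_none, fragment: 90-210, equivalents: none,
       transitions: [{tm: 53, dh: 300}]}
    - {name: Y123S_90_0.8, fragment: 90-210, equivalents: "0.8",
       partner: Y123S_90_none,
       transitions: [{tm: 43, dh: 300, amplitude: 0.5},
                     {tm: 59, dh: 300, amplitude: 0.5}]}
    - {name: S161I_90_none, fragment: 90-210, equivalents: none,
       transitions: [{tm: 56, dh: 300}]}
    - {name: S161I_90_0.8, fragment: 90-210, equivalents: "0.8",
       partner: S161I_90_none,
       transitions: [{tm: 46, dh: 400, amplitude: 0.5},
                     {tm: 54, dh: 400, amplitude: 0.5}]}
xanes:
  target: wt_81_0.8
  bound_fraction: 0.43
  edge: 7720
exafs:
  edge: 7709
  ef: 3
  excise_radius: 5
  shells: [[4, 2.02], [1, 2.21], [1, 1.85]]
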