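# Reference sloping arable-land profile for the simulated-erosion design:
# 20 cm cultivated horizon, two 10 cm subsoil layers, parent material
# below the 40 cm effective soil depth. Units: cm and cm/a.
plow_depth: 20
annual_erosion: 0.1
layers:
  - {label: "h0 (0-20 cm)", top_depth: 0, thickness: 20, material: cultivated}
  - {label: "20-30 cm", top_depth: 20, thickness: 10, material: subsoil}
  - {label: "30-40 cm", top_depth: 30, thickness: 10, material: subsoil}
  - {label: "parent (>40 cm)", top_depth: 40, thickness: 10, material: parent}
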