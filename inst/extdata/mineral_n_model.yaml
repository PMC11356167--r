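# Structural model of mineral-nitrogen drivers: erosion thickness and
# season act through total nitrogen, carbon content and the AMF and nifH
# communities. Matches mineral_n_path_spec().
blocks:
  erosion: [treatment_cm]
  season: [season_rainy]
  tn: [TN]
  carbon: [SOC, DOC]
  amf: [amf_dominance, amf_shannon]
  nifh: [nifh_dominance, nifh_shannon]
  mineraln: [NH4, NO3]
paths:
  - [erosion, tn]
  - [erosion, carbon]
  - [erosion, amf]
  - [erosion, nifh]
  - [season, amf]
  - [season, nifh]
  - [amf, nifh]
  - [tn, mineraln]
  - [carbon, mineraln]
  - [nifh, mineraln]
  - [amf, mineraln]
  - [erosion, mineraln]
  - [season, mineraln]
scheme: centroid
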