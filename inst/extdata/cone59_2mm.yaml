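# 2 mm stereotactic cone at 59 cm from the source
source:
  model: double
spectrum:
  mean_MeV: 6
  fwhm_fraction: 0.14
geometry:
  type: cone
  diameter_mm: 2
  cone_z: 59
  ssd: 100
  depth: 1.5
run:
  n: 100000
  seed: 20260928
  bin_width: 0.002
  scan: x
  emission_model: parallel
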