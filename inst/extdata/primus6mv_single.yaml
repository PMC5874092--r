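# PRIMUS 6 MV, single-Gaussian electron spot (FWHM 0.10 cm, conventional
# commissioning)
source:
  model: single
spectrum:
  mean_MeV: 6
  fwhm_fraction: 0.14
geometry:
  type: square
  side_cm: 0.5
  jaw_z: 22
  mlc_z: 31
  ssd: 100
  depth: 1.5
run:
  n: 100000
  seed: 20260928
  bin_width: 0.01
  scan: x
  emission_model: parallel
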