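# Late PANTHOS cohort (6 months): dense-core (Thio-S) conversion and glial
# engagement are high, DAPI detectability has dropped to the printed 67.8%.
name: panthos-6mo
channels: [mRFP, eGFP, CTSD, Abeta, DAPI, ThioS, GFAP, IbaI]
pixel_size: 0.15
psf_sigma: 0.2
noise: true
read_noise_sd: 0.02
photons_full_scale: 400
background: 0.02
geometry:
  soma_radius: 10.0
  nucleus_radius: 4.0
  field: 72.0
counts:    {AP: 0.0, AL: 0.5, paAL: 12.0, LY: 2.0}
size_um2:  {AP: 0.60, AL: 1.75, paAL: 2.50, LY: 0.50}
size_cv: 0.25
pH_mean:   {AP: 7.0, AL: 4.8, paAL: 6.6, LY: 4.8}
pH_sd:     {AP: 0.2, AL: 0.3, paAL: 0.3, LY: 0.3}
p_abeta:   {AP: 0.0, AL: 0.0, paAL: 0.0, LY: 0.0}
p_pla:     {AP: 0.0, AL: 0.0, paAL: 0.0, LY: 0.0}
panthos:
  stage_mix: {none: 0.0, i: 0.0, ii: 0.0, iii: 1.0}
  p_amyloid: 1.0
  p_thioS: 0.952
  p_gfap: 0.707
  p_ibai: 0.874
  p_isolated_plaque: 0.0905
  dapi: {normal: 0.328, condensed: 0.350, absent: 0.322}
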