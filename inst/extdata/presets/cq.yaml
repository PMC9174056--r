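# Chloroquine de-acidification scenario: control vesicle complement, but AL
# luminal pH shifted above the eGFP quench point, so ground-truth ALs render
# yellow/white and the classifier reads them as pa-AL. Color-class oracle
# equivalence intentionally does NOT hold for this preset.
name: cq
channels: [mRFP, eGFP, CTSD]
pixel_size: 0.1
psf_sigma: 0.15
noise: true
read_noise_sd: 0.02
photons_full_scale: 400
background: 0.02
geometry:
  soma_radius: 10.0
  nucleus_radius: 4.0
  tile: 24.0
counts:    {AP: 2.0, AL: 6.6, paAL: 2.1, LY: 4.0}
size_um2:  {AP: 0.60, AL: 0.74, paAL: 0.48, LY: 0.50}
size_cv: 0.25
pH_mean:   {AP: 7.0, AL: 6.7, paAL: 6.6, LY: 4.8}
pH_sd:     {AP: 0.2, AL: 0.2, paAL: 0.3, LY: 0.3}
pH_lo:     {AL: 6.4}
pH_hi:     {AL: 7.5}
p_abeta:   {AP: 0.0, AL: 0.0, paAL: 0.0, LY: 0.0}
p_pla:     {AP: 0.0, AL: 0.0, paAL: 0.0, LY: 0.0}
panthos:
  stage_mix: {none: 1.0, i: 0.0, ii: 0.0, iii: 0.0}
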