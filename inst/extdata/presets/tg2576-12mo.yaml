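# 12-month AD-model cortex: further pa-AL accumulation (17.2 per neuronal
# cross-section printed). The 12-month AL count and sizes are not printed;
# AL mean kept at the 5-month value and sizes nudged up (generator realism
# choices, see the methods vignette).
name: tg2576-12mo
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
counts:    {AP: 2.0, AL: 4.4, paAL: 17.2, LY: 4.0}
size_um2:  {AP: 0.60, AL: 1.80, paAL: 1.40, LY: 0.50}
size_cv: 0.25
pH_mean:   {AP: 7.0, AL: 4.8, paAL: 6.6, LY: 4.8}
pH_sd:     {AP: 0.2, AL: 0.3, paAL: 0.3, LY: 0.3}
p_abeta:   {AP: 0.0, AL: 0.0, paAL: 0.0, LY: 0.0}
p_pla:     {AP: 0.0, AL: 0.0, paAL: 0.0, LY: 0.0}
panthos:
  stage_mix: {none: 1.0, i: 0.0, ii: 0.0, iii: 0.0}
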