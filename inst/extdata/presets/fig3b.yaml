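# Four-fluorophore colocalization scenario: 5-month AD-model vesicle
# complement plus an amyloid/APP-beta-CTF antibody channel. Per-vesicle
# antibody-positivity probabilities are solved from the two printed
# constraints (88.6% of antibody-positive puncta are pa-AL; 40% of neurons
# contain at least one positive punctum) by Poisson thinning:
#   9.0*p_paAL + 4.4*p_AL = -ln(0.60) = 0.5108,  9.0*p_paAL / 0.5108 = 0.886
name: fig3b
channels: [mRFP, eGFP, CTSD, Abeta]
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
counts:    {AP: 2.0, AL: 4.4, paAL: 9.0, LY: 4.0}
size_um2:  {AP: 0.60, AL: 1.75, paAL: 1.30, LY: 0.50}
size_cv: 0.25
pH_mean:   {AP: 7.0, AL: 4.8, paAL: 6.6, LY: 4.8}
pH_sd:     {AP: 0.2, AL: 0.3, paAL: 0.3, LY: 0.3}
p_abeta:   {AP: 0.0, AL: 0.013224, paAL: 0.050286, LY: 0.0}
p_pla:     {AP: 0.0, AL: 0.0, paAL: 0.0, LY: 0.0}
panthos:
  stage_mix: {none: 1.0, i: 0.0, ii: 0.0, iii: 0.0}
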