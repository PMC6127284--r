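n_particles: 400
frac_stationary: 0.2
frac_slow_distal: 0.32
frac_slow_proximal: 0.32
frac_fast_distal: 0.08
frac_fast_proximal: 0.08
v_slow: 0.2
v_fast: 0.82
v_fast_cv: 0.18
diffusion_slow: 0.05
dendrite_length: 100.0
dendrite_width: 2.0
roi_centre: 50.0
roi_halfwidth: 2.5
pixel_size: 0.2
frame_interval: 15.0
duration: 180.0
psf_sigma: 0.25
photons_per_particle: 50.0
background_level: 5.0
noise_on: yes
seed: 1
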