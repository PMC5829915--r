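composition:
  heads_per_molecule: 2.0
  mix_ratio:
  - 1.0
  - 0.0
  molecules_per_filament: 30.0
  species_pair:
  - B
  - tail
conditions:
  actin_length_um: 15.0
  max_time_s: 500.0
  rescue_tau0_s: 0.01
  viscosity_mPas: 1.0
imaging:
  length_um_mean: 12.0
  length_um_sd: 2.0
  n_filaments_per_movie: 15.0
  n_movies: 1.0
  start_window_s: 60.0
optics:
  background_mean: 20.0
  frame_count: 100.0
  frame_interval_s: 2.0
  image_shape:
  - 256.0
  - 256.0
  photons_per_fluorophore_per_frame: 80.0
  pixel_size_nm: 130.0
  psf_sigma_nm: 140.0
  read_noise_sd: 2.0
quantification:
  detection_minimum_um: 0.15
  run_length_method: histogram_lsq
schema_version: 1.0
seed: 1.0
simulation:
  n_runs: 200.0
species:
  A:
    cycle_time_s: 1.2030075
    duty_ratio: 0.05
    name: NM2A
    speed_sd_nm_s: 75.0
    step_size_nm: 8.0
    unloaded_speed_nm_s: 133.0
  B:
    cycle_time_s: 0.8088979
    duty_ratio: 0.23
    name: NM2B
    speed_sd_nm_s: 21.0
    step_size_nm: 8.0
    unloaded_speed_nm_s: 43.0
tracking:
  estimated_diameter_nm: 1000.0
  gap_closing_max_nm: 500.0
  linking_max_nm: 1000.0
  max_frame_gap: 2.0
  min_displacement_nm: 150.0
  quality_threshold: 100.0
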