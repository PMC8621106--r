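# Two-condition synthetic demonstration: "glass" vs "graphene" fields whose
# generative events-per-cluster means differ, analyzed with one shared
# cluster configuration. Run with:
#   Rscript inst/cli/smlmpipe.R run --config inst/extdata/demo_config.yaml \
#     --out runs/demo --seed 5
seed: 5
out: runs/demo
reference: glass
camera:
  frame_count: 200
  pixel_size_nm: 160
  psf_sigma_nm: 150
blink:
  k_on: 0.002
  k_off: 0.5
  initial_on_fraction: 0.1
  activation_boost: 1
localize:
  use_ground_truth: true
  precision_nm: 10
drift:
  n_subsets: 4
  recon_bin_nm: 20
cluster:
  bin_nm: 20
  kernel_px: 7
  density_threshold: 8
  scale_factor: 5
  min_molecules: 3
photophysics:
  bin_frames: 20
  frame_rate_hz: 33
conditions:
  glass:
    simulate:
      roi_width_nm: 5000
      roi_height_nm: 5000
      cluster_rate: 5
      molecules_per_cluster_mean: 54
      cluster_sigma_nm: 12
      background_molecule_rate: 5
      min_center_sep_nm: 300
  graphene:
    simulate:
      roi_width_nm: 5000
      roi_height_nm: 5000
      cluster_rate: 5
      molecules_per_cluster_mean: 92.5
      cluster_sigma_nm: 12
      background_molecule_rate: 5
      min_center_sep_nm: 300
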