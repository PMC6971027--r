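# Reference fast-mode run: 24 carriers filling the 1.1-1.4 kHz band at a
# 3183 fps camera (13 vol/s), 24 light sheets from the 200/50 mm mirror pair.
mirror:
  L_mm: 200
  S_mm: 50
  alpha_rad: 1.0e-3
  R: 0.998
  dtheta_rad: 0.04
source:
  lambda_nm: 532
  dlambda_nm: 0.0445
  lineshape: gaussian
sheets:
  n_keep: 24
  z0_um: 1.2
  w_ls_um: 1.5
plan:
  n_channels: 24
  f_cam: 3183
  f_vol: 13
  f_H: 1399
  waveform: cosine
phantom:
  kind: beads
  n_beads: 8
  bead_diameter_um: 1.0
  placement: tilted_plane_45deg
  grid_dim: [32, 24, 32]
  voxel_um: [0.9, 1.0, 1.0]
recon:
  boxcar_width: 3
rng_seed: 1
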