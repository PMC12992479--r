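# data.table non-standard-evaluation column names
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", ".BY", "trial_uid", "participant", "group", "block",
  "trial", "hand", "target_deg", "channel", "rotation_on", "field_on",
  "rot_estimate", "dyn_estimate", "aim_bias", "movement_time",
  "fx", "fy", "x", "y", "vx", "vy", "onset", "offset", "peak_vel",
  "ballistic_end", "force", "u", "phase", "bin", "value", "N",
  "baseline_block", ".bl_mean", "rmse_bc", "ide_deg_bc", "iee_deg_bc",
  "fee_cm_bc", "rmse", "ide_deg", "iee_deg", "fee_cm", "x_hat",
  "f_peak", "f_ballistic", "f_end"))
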