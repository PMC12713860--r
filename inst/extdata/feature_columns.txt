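# edasleep feature-column manifest v1
eda_mode
eda_median
eda_absmax
eda_line_length
eda_q10
eda_q75
eda_svd_entropy
eda_nl_energy
eda_shannon_entropy
det_mode
det_median
det_absmax
det_line_length
det_q10
det_q75
det_svd_entropy
det_nl_energy
det_shannon_entropy
d1eda_mean
d1eda_var
d1eda_median
d1eda_n_pos
d2eda_mean
d2eda_var
d2eda_median
d2eda_n_pos
d1det_mean
d1det_var
d1det_median
d1det_n_pos
d2det_mean
d2det_var
d2det_median
d2det_n_pos
eda_psd_max
eda_psd_fmax
eda_fishers_g
det_psd_max
det_psd_fmax
det_fishers_g
dl1_max
dl1_mean
dl1_sd
dl1_median
dl1_norm
dl1_npos_frac
dl2_max
dl2_mean
dl2_sd
dl2_median
dl2_norm
dl2_npos_frac
dl3_max
dl3_mean
dl3_sd
dl3_median
dl3_norm
dl3_npos_frac
dl4_max
dl4_mean
dl4_sd
dl4_median
dl4_norm
dl4_npos_frac
eda_lyapunov
eda_env_max
eda_env_min
det_lyapunov
det_env_max
det_env_min
diff_xcorr_sum
diff_conv_max
event_frac
event_energy
storm_frac
storm_energy
sex
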