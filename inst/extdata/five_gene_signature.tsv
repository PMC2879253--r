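gene	probe_id	rf_rank	mean_expr_R	mean_expr_CCR	fold_change_array	fold_change_qpcr	platform_r
ABTB2	213497_at	12	119.8	89.7	1.34	3.11	0.76
IL7R	205798_at	43	292.0	542.7	0.54	0.47	0.92
LGALS8	208936_x_at	288	197.4	231.8	0.85	0.37	0.56
PLAC8	219014_at	297	530.4	979.5	0.54	0.22	0.90
FAM13A1	217047_s_at	356	70.0	84.0	0.83	0.30	0.69
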