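{
  "comment": "Ground-truth hemodynamic factors for the bundled 90-min filament tMCAO scenario. CBV factors are relative to baseline; CBFv in mm/s; dsc_* factors are the DSC-MRI ipsi/contra truth. Times in minutes; occlusion onset at t = 0, filament retraction at t = 90.",
  "epochs": [
    {"name": "baseline",   "t_start": -30, "t_end": 0,   "cbv_ipsi": 1.00, "cbv_contra": 1.0, "cbfv_ipsi": 14.6, "cbfv_contra": 14.6, "dsc_cbv_ipsi": 1.00, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 1.00, "dsc_cbf_contra": 1.0},
    {"name": "occlusion",  "t_start": 0,   "t_end": 90,  "cbv_ipsi": 0.50, "cbv_contra": 1.0, "cbfv_ipsi": 9.1,  "cbfv_contra": 15.9, "dsc_cbv_ipsi": 0.56, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 0.20, "dsc_cbf_contra": 1.0},
    {"name": "transient",  "t_start": 90,  "t_end": 95,  "cbv_ipsi": 0.88, "cbv_contra": 1.0, "cbfv_ipsi": 14.0, "cbfv_contra": 15.5, "dsc_cbv_ipsi": 0.70, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 0.50, "dsc_cbf_contra": 1.0},
    {"name": "post_early", "t_start": 95,  "t_end": 120, "cbv_ipsi": 0.88, "cbv_contra": 1.0, "cbfv_ipsi": 14.0, "cbfv_contra": 15.5, "dsc_cbv_ipsi": 0.75, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 0.55, "dsc_cbf_contra": 1.0},
    {"name": "post_1h",    "t_start": 120, "t_end": 180, "cbv_ipsi": 0.81, "cbv_contra": 1.0, "cbfv_ipsi": 13.4, "cbfv_contra": 15.5, "dsc_cbv_ipsi": 0.80, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 0.66, "dsc_cbf_contra": 1.0},
    {"name": "post_2h",    "t_start": 180, "t_end": 240, "cbv_ipsi": 0.78, "cbv_contra": 1.0, "cbfv_ipsi": 12.8, "cbfv_contra": 15.5, "dsc_cbv_ipsi": 0.85, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 0.72, "dsc_cbf_contra": 1.0},
    {"name": "post_3h",    "t_start": 240, "t_end": 300, "cbv_ipsi": 0.80, "cbv_contra": 1.0, "cbfv_ipsi": 12.2, "cbfv_contra": 15.5, "dsc_cbv_ipsi": 0.81, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 0.65, "dsc_cbf_contra": 1.0}
  ],
  "transient": {"intercept": 1.35, "slope_per_min": -0.094, "duration_min": 5},
  "gaps": [[-14, 10], [88, 99]]
}
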