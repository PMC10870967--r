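{
  "comment": "Identity scenario: every factor at its baseline value over the full experimental span. Used for symmetry and conservation checks.",
  "epochs": [
    {"name": "baseline",  "t_start": -30, "t_end": 0,   "cbv_ipsi": 1.0, "cbv_contra": 1.0, "cbfv_ipsi": 14.6, "cbfv_contra": 14.6, "dsc_cbv_ipsi": 1.0, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 1.0, "dsc_cbf_contra": 1.0},
    {"name": "sham",      "t_start": 0,   "t_end": 300, "cbv_ipsi": 1.0, "cbv_contra": 1.0, "cbfv_ipsi": 14.6, "cbfv_contra": 14.6, "dsc_cbv_ipsi": 1.0, "dsc_cbv_contra": 1.0, "dsc_cbf_ipsi": 1.0, "dsc_cbf_contra": 1.0}
  ],
  "transient": null,
  "gaps": []
}
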