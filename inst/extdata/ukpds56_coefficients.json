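{
  "comment": "UKPDS Risk Engine coefficients for 10-year CHD risk in type 2 diabetes, transcribed from the published reference (Stevens et al. 2001, Clinical Science 101:671-679, UKPDS 56). Continuous factors enter as coefficient^((value - center)/scale); binary factors as coefficient^{0,1}. lipid_ratio is ln(total cholesterol / HDL cholesterol).",
  "q0": 0.0112,
  "d": 1.078,
  "factors": [
    {"name": "age_at_diagnosis", "coefficient": 1.059, "center": 55.0,  "scale": 1,  "type": "continuous"},
    {"name": "female",           "coefficient": 0.525, "center": 0,     "scale": 1,  "type": "binary"},
    {"name": "afro_caribbean",   "coefficient": 0.390, "center": 0,     "scale": 1,  "type": "binary"},
    {"name": "smoker",           "coefficient": 1.350, "center": 0,     "scale": 1,  "type": "binary"},
    {"name": "hba1c",            "coefficient": 1.183, "center": 6.72,  "scale": 1,  "type": "continuous"},
    {"name": "sbp",              "coefficient": 1.088, "center": 135.7, "scale": 10, "type": "continuous"},
    {"name": "lipid_ratio",      "coefficient": 3.845, "center": 1.59,  "scale": 1,  "type": "continuous"}
  ]
}
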