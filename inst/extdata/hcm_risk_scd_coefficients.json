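{
  "model": "HCM Risk-SCD 5-year sudden cardiac death risk (2014 ESC guidelines)",
  "source": "O'Mahony C et al. A novel clinical risk prediction model for sudden cardiac death in hypertrophic cardiomyopathy (HCM Risk-SCD). Eur Heart J 2014;35:2010-2020.",
  "baseline_survival_5yr": 0.998,
  "coefficients": {
    "max_wall_thickness_mm": 0.15939858,
    "max_wall_thickness_mm_squared": -0.00294271,
    "la_diameter_mm": 0.0259082,
    "max_lvot_gradient_mmHg": 0.00446131,
    "fh_scd": 0.4583082,
    "nsvt": 0.82639195,
    "syncope": 0.71650361,
    "age_years": -0.01799934
  },
  "variable_units": {
    "max_wall_thickness_mm": "mm",
    "la_diameter_mm": "mm",
    "max_lvot_gradient_mmHg": "mmHg",
    "fh_scd": "0/1",
    "nsvt": "0/1",
    "syncope": "0/1",
    "age_years": "years"
  }
}
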