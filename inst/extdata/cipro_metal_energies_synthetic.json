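[
  {
    "label": "water",
    "role": "water",
    "charge": 0,
    "formula": "H2O",
    "e_pcm_sp": -76.43,
    "g_thermal_corr": 0.003
  },
  {
    "label": "ciprofloxacin_cation",
    "role": "fq_cation",
    "charge": 1,
    "formula": "C17H19FN3O3",
    "e_pcm_sp": -1010.5,
    "g_thermal_corr": 0.38
  },
  {
    "label": "Al_hexahydrate",
    "role": "metal_hexahydrate",
    "charge": 3,
    "metal": "Al",
    "formula": "AlH12O6",
    "e_pcm_sp": -700.9,
    "g_thermal_corr": 0.11
  },
  {
    "label": "ciprofloxacin_Al_chelate",
    "role": "chelate_complex",
    "charge": 4,
    "metal": "Al",
    "formula": "C17H27FN3O7Al",
    "e_pcm_sp": -1558.59165698209,
    "g_thermal_corr": 0.51
  },
  {
    "label": "Mg_hexahydrate",
    "role": "metal_hexahydrate",
    "charge": 2,
    "metal": "Mg",
    "formula": "MgH12O6",
    "e_pcm_sp": -658.3,
    "g_thermal_corr": 0.11
  },
  {
    "label": "ciprofloxacin_Mg_chelate",
    "role": "chelate_complex",
    "charge": 3,
    "metal": "Mg",
    "formula": "C17H27FN3O7Mg",
    "e_pcm_sp": -1515.97444608727,
    "g_thermal_corr": 0.51
  },
  {
    "label": "Ca_hexahydrate",
    "role": "metal_hexahydrate",
    "charge": 2,
    "metal": "Ca",
    "formula": "CaH12O6",
    "e_pcm_sp": -1135.5,
    "g_thermal_corr": 0.11
  },
  {
    "label": "ciprofloxacin_Ca_chelate",
    "role": "chelate_complex",
    "charge": 3,
    "metal": "Ca",
    "formula": "C17H27FN3O7Ca",
    "e_pcm_sp": -1993.16456575877,
    "g_thermal_corr": 0.51
  }
]
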