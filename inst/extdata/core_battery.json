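[
  {"name": "ATP production from glucose", "category": "carbohydrates",
   "allowed_uptakes": ["glucose", "o2"], "objective": {"atpase": 1.0}},
  {"name": "ATP production from lactate", "category": "carboxylic acids",
   "allowed_uptakes": ["lactate", "o2"], "objective": {"atpase": 1.0}},
  {"name": "ATP production from acetoacetate", "category": "carboxylic acids",
   "allowed_uptakes": ["acetoacetate", "o2"], "objective": {"atpase": 1.0}},
  {"name": "ATP production from acetate", "category": "carboxylic acids",
   "allowed_uptakes": ["acetate", "o2"], "objective": {"atpase": 1.0}},
  {"name": "ATP production from palmitate", "category": "lipids",
   "allowed_uptakes": ["palmitate", "o2"], "objective": {"atpase": 1.0}},
  {"name": "ATP production from oleate", "category": "lipids",
   "allowed_uptakes": ["oleate", "o2"], "objective": {"atpase": 1.0}},
  {"name": "ATP production from docosahexaenoate", "category": "lipids",
   "allowed_uptakes": ["dha", "o2"], "objective": {"atpase": 1.0}},
  {"name": "Glycogen formation from glucose", "category": "carbohydrates",
   "allowed_uptakes": ["glucose", "o2"], "objective": {"glycogen_synthesis": 0.1}},
  {"name": "Ketone body degradation", "category": "carboxylic acids",
   "allowed_uptakes": ["acetoacetate", "o2"], "objective": {"ox_acetoacetate": 0.5}},
  {"name": "Ceramide synthesis", "category": "lipids",
   "allowed_uptakes": ["palmitate", "alpha_linoleate", "dha", "glucose", "o2"],
   "objective": {"target_cer": 0.001}},
  {"name": "Cardiolipin synthesis", "category": "lipids",
   "allowed_uptakes": ["palmitate", "alpha_linoleate", "dha", "glucose", "o2"],
   "objective": {"target_cl": 0.002}},
  {"name": "Phosphatidylcholine synthesis", "category": "lipids",
   "allowed_uptakes": ["palmitate", "alpha_linoleate", "dha", "glucose", "o2"],
   "objective": {"target_pc": 0.005}},
  {"name": "Phosphatidylethanolamine synthesis", "category": "lipids",
   "allowed_uptakes": ["palmitate", "alpha_linoleate", "dha", "glucose", "o2"],
   "objective": {"target_pe": 0.003}},
  {"name": "Sphingomyelin synthesis", "category": "lipids",
   "allowed_uptakes": ["palmitate", "alpha_linoleate", "dha", "glucose", "o2"],
   "objective": {"target_sm": 0.001}},
  {"name": "NADPH production", "category": "nucleic acids and redox",
   "allowed_uptakes": ["glucose", "o2"], "objective": {"nadph_drain": 1e-05}}
]
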