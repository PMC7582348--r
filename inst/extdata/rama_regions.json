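[
  {"name": "alpha_favored", "class": "favored",
   "phi": [-140, -140, -120, -30, -30, -120],
   "psi": [-60, 10, 30, 30, -70, -70]},
  {"name": "beta_favored", "class": "favored",
   "phi": [-170, -170, -50, -50],
   "psi": [85, 175, 175, 85]},
  {"name": "beta_favored_wrap", "class": "favored",
   "phi": [-170, -170, -50, -50],
   "psi": [-180, -160, -160, -180]},
  {"name": "left_alpha_favored", "class": "favored",
   "phi": [35, 35, 90, 90],
   "psi": [0, 75, 75, 0]},
  {"name": "alpha_allowed", "class": "allowed",
   "phi": [-160, -160, -20, -20],
   "psi": [-90, 50, 50, -90]},
  {"name": "beta_allowed", "class": "allowed",
   "phi": [-180, -180, -40, -40],
   "psi": [65, 180, 180, 65]},
  {"name": "beta_allowed_wrap", "class": "allowed",
   "phi": [-180, -180, -40, -40],
   "psi": [-180, -150, -150, -180]},
  {"name": "left_alpha_allowed", "class": "allowed",
   "phi": [25, 25, 100, 100],
   "psi": [-10, 90, 90, -10]}
]
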