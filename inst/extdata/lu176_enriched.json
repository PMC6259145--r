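{
  "comment": "Enriched Lu2O3 target for direct Lu-177 production. Masses on the integer mass-number scale; weight percents from the enrichment certificate; mass is on the element (Lu) basis.",
  "target": {
    "element": "Lu",
    "oxide_formula": "Lu2O3",
    "mass_g": 0.001,
    "impurities": [
      {"element": "La", "ppm": 66},
      {"element": "Yb", "ppm": 13},
      {"element": "Tm", "ppm": 0.5, "bound": "<1"},
      {"element": "Er", "ppm": 17},
      {"element": "Dy", "ppm": 4},
      {"element": "Gd", "ppm": 6},
      {"element": "Eu", "ppm": 20},
      {"element": "Sm", "ppm": 2},
      {"element": "Nd", "ppm": 1}
    ]
  },
  "isotopes": [
    {"symbol": "Lu-176", "atomic_mass": 176, "half_life": "stable", "weight_percent": 74.1},
    {"symbol": "Lu-175", "atomic_mass": 175, "half_life": "stable", "weight_percent": 25.9}
  ],
  "products": [
    {"symbol": "Lu-177",  "atomic_mass": 177, "half_life": "6.71d",  "branches": {"beta-to-Hf-177": 1}},
    {"symbol": "Lu-177m", "atomic_mass": 177, "half_life": "160.7d", "branches": {"IT-to-Lu-177": 1}},
    {"symbol": "Tm-173",  "atomic_mass": 173, "half_life": "8.2h",   "branches": {"beta-to-Yb-173": 1}},
    {"symbol": "Lu-176m", "atomic_mass": 176, "half_life": "3.7h",   "branches": {"IT-to-Lu-176": 1}},
    {"symbol": "Tm-172",  "atomic_mass": 172, "half_life": "2.6d",   "branches": {"beta-to-Yb-172": 1}}
  ],
  "channels": [
    {"label": "Lu-1", "parent": "Lu-176", "product": "Lu-177",  "sigma0": 2300, "I0": 1200,
     "non_1v": true, "k_factor": 1.74, "elemental_loss": true,
     "comment": "non-1/v nuclide: effective thermal cross-section is k*sigma0"},
    {"label": "Lu-2", "parent": "Lu-176", "product": "Lu-177m", "sigma0": 2, "I0": 3,
     "elemental_loss": false,
     "comment": "long-lived product stays in the Lu elemental pool during irradiation; its isomeric feed of Lu-177 is recorded but excluded from the Lu-177 balance"},
    {"label": "Lu-3", "parent": "Lu-176", "product": "Tm-173", "sigma0": 0.002, "I0": 0,
     "kind": "n-alpha", "sigma0_bound": "<2e-3", "elemental_loss": true},
    {"label": "Lu-4", "parent": "Lu-175", "product": "Lu-176m", "sigma0": 16, "I0": 550,
     "elemental_loss": false},
    {"label": "Lu-5", "parent": "Lu-175", "product": "Lu-176", "sigma0": 9, "I0": 300,
     "elemental_loss": false},
    {"label": "Lu-6", "parent": "Lu-175", "product": "Tm-172", "sigma0": 1e-05, "I0": 0,
     "kind": "n-alpha", "sigma0_bound": "<1e-5", "elemental_loss": true}
  ]
}
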