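{
  "comment": "Enriched Yb2O3 target for indirect Lu-177 production via Yb-176(n,g)Yb-177 -> beta -> Lu-177. Isotopes certified as '<0.01%' are stored at the midpoint 0.005 with the bound recorded. Elemental Lu impurity assumed of natural isotopic abundance. Mass on the element (Yb) basis.",
  "target": {
    "element": "Yb",
    "oxide_formula": "Yb2O3",
    "mass_g": 0.001,
    "impurities": [
      {"element": "Er", "ppm": 50},
      {"element": "Tm", "ppm": 50},
      {"element": "Lu", "ppm": 50,
       "abundances": {"Lu-175": 97.41, "Lu-176": 2.59}}
    ]
  },
  "isotopes": [
    {"symbol": "Yb-176", "atomic_mass": 176, "half_life": "stable", "weight_percent": 97.6},
    {"symbol": "Yb-174", "atomic_mass": 174, "half_life": "stable", "weight_percent": 1.93},
    {"symbol": "Yb-173", "atomic_mass": 173, "half_life": "stable", "weight_percent": 0.18},
    {"symbol": "Yb-172", "atomic_mass": 172, "half_life": "stable", "weight_percent": 0.22},
    {"symbol": "Yb-171", "atomic_mass": 171, "half_life": "stable", "weight_percent": 0.07},
    {"symbol": "Yb-170", "atomic_mass": 170, "half_life": "stable", "weight_percent": 0.005, "bound": "<0.01"},
    {"symbol": "Yb-168", "atomic_mass": 168, "half_life": "stable", "weight_percent": 0.005, "bound": "<0.01"}
  ],
  "products": [
    {"symbol": "Yb-177", "atomic_mass": 177, "half_life": "1.911h", "branches": {"beta-to-Lu-177": 1}},
    {"symbol": "Yb-175", "atomic_mass": 175, "half_life": "4.2d",   "branches": {"beta-to-Lu-175": 1}},
    {"symbol": "Yb-169", "atomic_mass": 169, "half_life": "32d",    "branches": {"EC-to-Tm-169": 1}},
    {"symbol": "Lu-177", "atomic_mass": 177, "half_life": "6.71d",  "branches": {"beta-to-Hf-177": 1}},
    {"symbol": "Lu-175", "atomic_mass": 175, "half_life": "stable"}
  ],
  "channels": [
    {"label": "Yb-1", "parent": "Yb-176", "product": "Yb-177", "sigma0": 3.0,  "I0": 8,
     "elemental_loss": true,
     "comment": "production chain: Yb-177 (1.911 h) beta-decays to Lu-177"},
    {"label": "Yb-2", "parent": "Yb-174", "product": "Yb-175", "sigma0": 63.0, "I0": 60,
     "elemental_loss": true,
     "comment": "stable-carrier source: Yb-175 (4.2 d) beta-decays to stable Lu-175"},
    {"label": "Yb-3", "parent": "Yb-173", "product": "Yb-174", "sigma0": 17.4, "I0": 400,
     "elemental_loss": false},
    {"label": "Yb-4", "parent": "Yb-172", "product": "Yb-173", "sigma0": 1.3,  "I0": 25,
     "elemental_loss": false},
    {"label": "Yb-5", "parent": "Yb-171", "product": "Yb-172", "sigma0": 50.0, "I0": 320,
     "elemental_loss": false},
    {"label": "Yb-6", "parent": "Yb-170", "product": "Yb-171", "sigma0": 10.0, "I0": 300,
     "elemental_loss": false},
    {"label": "Yb-7", "parent": "Yb-168", "product": "Yb-169", "sigma0": 2300, "I0": 2100,
     "elemental_loss": true}
  ]
}
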