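{
  "site": "Kidd Creek",
  "_comment": "Published site values: fracture-fluid observations from the Kidd Creek mine (Timmins, Ontario). All numbers are printed measurements or documented model defaults.",
  "temperature_C": 25,
  "water_d2H": -36,
  "acetate_d2H": [-142, -130],
  "acetate_d13C": [-10.0, -6.6],
  "acetate_conc_M": 1.3e-3,
  "threshold_permil": 50,
  "concentrations_M": {
    "acetate": 1.3e-3,
    "sulfate": 620e-6,
    "bicarbonate": 57e-6,
    "sulfide": 10e-9,
    "methane": 2.1e-3,
    "water": 1
  },
  "gammas": {
    "acetate": 1, "sulfate": 1, "bicarbonate": 1, "sulfide": 1,
    "methane": 1, "water": 1
  },
  "reactions": [
    {
      "name": "sulfate_reduction",
      "dG0_J_mol": -47600,
      "stoichiometry": {"acetate": -1, "sulfate": -1, "bicarbonate": 2, "sulfide": 1}
    },
    {
      "name": "methanogenesis",
      "dG0_J_mol": -31000,
      "stoichiometry": {"acetate": -1, "water": -1, "methane": 1, "bicarbonate": 1}
    }
  ],
  "maintenance_powers_W_cell": [1e-21, 1e-20, 1e-19, 1e-18, 1e-17],
  "radiolysis": {
    "U_ppm": 1.5,
    "Th_ppm": 6.7,
    "K_pct": 1.7,
    "S_alpha": 1.5,
    "porosity": 0.01,
    "rho_bulk_kg_dm3": 2.98,
    "rho_water_g_cm3": 1.11,
    "rho_rock_g_cm3": 2.98,
    "G_nM_per_J": 6
  },
  "eie": {
    "anchors": [
      {"temperature_K": 298.15, "epsilon_permil": -192},
      {"temperature_K": 523.15, "epsilon_permil": -108}
    ],
    "salt_multiplier": 1.015
  }
}
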