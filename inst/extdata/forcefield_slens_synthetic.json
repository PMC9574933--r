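{
  "comment": [
    "SYNTHETIC force-field table for SLEnS in water.",
    "The pairwise repulsion/cutoff matrices and the heavy-atom bond-length",
    "rule follow the published alkyl-sulfate parameterization scheme this",
    "package targets (water bead = 2 H2O, per-pair cutoffs from bead molar",
    "volumes relative to water, Groot-Warren baseline a_WW = 25 at reduced",
    "density 3), but the numerical entries are a reconstruction, NOT a",
    "verbatim transcription of the original reference tables, which are not",
    "redistributed here. Edit this file to substitute a transcribed table;",
    "every operation in the package is parametric in it.",
    "Species: W water (2 H2O); CT terminal alkyl [CH3CH2]; CM mid alkyl",
    "[CH2CH2]; EO ethoxy [OCH2CH2]; ES sulfate head [OSO3]-; Na hydrated",
    "sodium counterion (Na+ + 2 H2O)."
  ],
  "species": ["W", "CT", "CM", "EO", "ES", "Na"],
  "water_species": "W",
  "charges": {"W": 0, "CT": 0, "CM": 0, "EO": 0, "ES": -1, "Na": 1},
  "heavy_atoms": {"W": 2, "CT": 2, "CM": 2, "EO": 3, "ES": 4, "Na": 1},
  "molar_masses_gmol": {"W": 36.03, "CT": 29.06, "CM": 28.05, "EO": 44.05,
                        "ES": 96.06, "Na": 22.99},
  "repulsion": [
    [25, 45, 45, 28, 25, 25],
    [45, 25, 25, 35, 50, 50],
    [45, 25, 25, 35, 50, 50],
    [28, 35, 35, 25, 28, 28],
    [25, 50, 50, 28, 35, 25],
    [25, 50, 50, 28, 25, 25]
  ],
  "cutoff": [
    [1.0,    1.0085, 0.982,  1.0125, 1.0825, 1.0175],
    [1.0085, 1.017,  0.9905, 1.021,  1.091,  1.026],
    [0.982,  0.9905, 0.964,  0.9945, 1.0645, 0.9995],
    [1.0125, 1.021,  0.9945, 1.025,  1.095,  1.03],
    [1.0825, 1.091,  1.0645, 1.095,  1.165,  1.1],
    [1.0175, 1.026,  0.9995, 1.03,   1.1,    1.035]
  ],
  "bond_rule": {"type": "linear_heavy", "coefficient": 0.1125},
  "bonds": {"C": 150},
  "angles": {"D": 5, "theta0": 180},
  "thermostat": {"sigma": 3, "kT": 1, "dt": 0.01},
  "electrostatics": {
    "enabled": true,
    "slater_beta": 0.929,
    "relative_permittivity": 78.3
  },
  "molecule": {
    "tail": ["CT", "CM", "CM", "CM", "CM", "CM"],
    "ethoxy": "EO",
    "head": "ES",
    "counterion": "Na"
  }
}
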