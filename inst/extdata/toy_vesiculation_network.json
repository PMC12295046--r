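{
  "format": "omvflux-network",
  "version": 1,
  "compartments": {
    "c": "c",
    "e": "e",
    "p": "p"
  },
  "biomass_reaction": "BIOMASS",
  "genes": [
    "gbio1",
    "gbio1c",
    "gbio2",
    "gbio2b",
    "gbio3",
    "gcolipa",
    "gdrain",
    "gpe",
    "gpg",
    "gT"
  ],
  "metabolites": [
    {
      "id": "carbon_e",
      "name": "carbon source (extracellular)",
      "compartment": "e"
    },
    {
      "id": "carbon_c",
      "name": "carbon source (cytosol)",
      "compartment": "c"
    },
    {
      "id": "prec_c",
      "name": "biomass precursor",
      "compartment": "c"
    },
    {
      "id": "waste_c",
      "name": "waste",
      "compartment": "c"
    },
    {
      "id": "pe160_c",
      "name": "pe160 (cytosol)",
      "compartment": "c"
    },
    {
      "id": "pe160_p",
      "name": "pe160 (periplasm)",
      "compartment": "p"
    },
    {
      "id": "pg160_c",
      "name": "pg160 (cytosol)",
      "compartment": "c"
    },
    {
      "id": "pg160_p",
      "name": "pg160 (periplasm)",
      "compartment": "p"
    },
    {
      "id": "colipa_c",
      "name": "colipa (cytosol)",
      "compartment": "c"
    },
    {
      "id": "colipa_p",
      "name": "colipa (periplasm)",
      "compartment": "p"
    }
  ],
  "reactions": [
    {
      "id": "EX_carbon",
      "name": "EX_carbon",
      "stoichiometry": {
        "carbon_e": -1
      },
      "lower_bound": -10,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    },
    {
      "id": "T_carbon",
      "name": "T_carbon",
      "stoichiometry": {
        "carbon_e": -1,
        "carbon_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "gT",
      "objective_coefficient": 0
    },
    {
      "id": "BIOMASS",
      "name": "BIOMASS",
      "stoichiometry": {
        "prec_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 1
    },
    {
      "id": "DRAIN",
      "name": "DRAIN",
      "stoichiometry": {
        "carbon_c": -1,
        "waste_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "gdrain",
      "objective_coefficient": 0
    },
    {
      "id": "DM_waste",
      "name": "DM_waste",
      "stoichiometry": {
        "waste_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    },
    {
      "id": "R_bio1",
      "name": "R_bio1",
      "stoichiometry": {
        "carbon_c": -1,
        "prec_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 2,
      "gpr": "gbio1 and gbio1c",
      "objective_coefficient": 0
    },
    {
      "id": "R_bio2",
      "name": "R_bio2",
      "stoichiometry": {
        "carbon_c": -1,
        "prec_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 4,
      "gpr": "gbio2 or gbio2b",
      "objective_coefficient": 0
    },
    {
      "id": "R_bio3",
      "name": "R_bio3",
      "stoichiometry": {
        "carbon_c": -1,
        "prec_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 2,
      "gpr": "gbio3",
      "objective_coefficient": 0
    },
    {
      "id": "SYN_pe160",
      "name": "SYN_pe160",
      "stoichiometry": {
        "carbon_c": -1,
        "pe160_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "gpe",
      "objective_coefficient": 0
    },
    {
      "id": "TR_pe160",
      "name": "TR_pe160",
      "stoichiometry": {
        "pe160_c": -1,
        "pe160_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    },
    {
      "id": "SK_pe160",
      "name": "SK_pe160",
      "stoichiometry": {
        "pe160_p": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    },
    {
      "id": "SYN_pg160",
      "name": "SYN_pg160",
      "stoichiometry": {
        "carbon_c": -1,
        "pg160_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "gpg",
      "objective_coefficient": 0
    },
    {
      "id": "TR_pg160",
      "name": "TR_pg160",
      "stoichiometry": {
        "pg160_c": -1,
        "pg160_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    },
    {
      "id": "SK_pg160",
      "name": "SK_pg160",
      "stoichiometry": {
        "pg160_p": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    },
    {
      "id": "SYN_colipa",
      "name": "SYN_colipa",
      "stoichiometry": {
        "carbon_c": -1,
        "colipa_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "gcolipa",
      "objective_coefficient": 0
    },
    {
      "id": "TR_colipa",
      "name": "TR_colipa",
      "stoichiometry": {
        "colipa_c": -1,
        "colipa_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    },
    {
      "id": "SK_colipa",
      "name": "SK_colipa",
      "stoichiometry": {
        "colipa_p": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gpr": "",
      "objective_coefficient": 0
    }
  ]
}
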