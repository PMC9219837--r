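{
  "description": "In-silico analogs of the engineered GABA and butyrolactam strain lineages. Overexpression (Ptuf promoter swaps) is encoded as an equality constraint at 2-fold the wild-type canonical flux; deletions fix bounds to zero; the gabP->potE transport rewiring closes GABA uptake; glyoxylate-shunt activation (observed as aceA/aceB upregulation in the sucCD deletant) opens the aceA/aceB bounds.",
  "series": [
    {
      "label": "GABA-1",
      "product": "EX_gaba",
      "edits": []
    },
    {
      "label": "GABA-2",
      "product": "EX_gaba",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"}
      ]
    },
    {
      "label": "GABA-3",
      "product": "EX_gaba",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"},
        {"type": "fix_flux_multiple", "rxn": "ICD", "factor": 2.0,
         "label": "Ptuf-icd"}
      ]
    },
    {
      "label": "GABA-4",
      "product": "EX_gaba",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"},
        {"type": "fix_flux_multiple", "rxn": "ICD", "factor": 2.0,
         "label": "Ptuf-icd"},
        {"type": "knockout", "rxn": "SUCOAS", "label": "delta-sucCD"},
        {"type": "set_bounds", "rxn": "ACEA", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceA)"},
        {"type": "set_bounds", "rxn": "ACEB", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceB)"}
      ]
    },
    {
      "label": "GABA-5",
      "product": "EX_gaba",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"},
        {"type": "fix_flux_multiple", "rxn": "ICD", "factor": 2.0,
         "label": "Ptuf-icd"},
        {"type": "knockout", "rxn": "SUCOAS", "label": "delta-sucCD"},
        {"type": "set_bounds", "rxn": "ACEA", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceA)"},
        {"type": "set_bounds", "rxn": "ACEB", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceB)"},
        {"type": "knockout", "rxn": "GABA_SHUNT_T", "label": "delta-gabT"},
        {"type": "knockout", "rxn": "GABA_SHUNT_D", "label": "delta-gabD"}
      ]
    },
    {
      "label": "GABA-6",
      "product": "EX_gaba",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"},
        {"type": "fix_flux_multiple", "rxn": "ICD", "factor": 2.0,
         "label": "Ptuf-icd"},
        {"type": "knockout", "rxn": "SUCOAS", "label": "delta-sucCD"},
        {"type": "set_bounds", "rxn": "ACEA", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceA)"},
        {"type": "set_bounds", "rxn": "ACEB", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceB)"},
        {"type": "knockout", "rxn": "GABA_SHUNT_T", "label": "delta-gabT"},
        {"type": "knockout", "rxn": "GABA_SHUNT_D", "label": "delta-gabD"},
        {"type": "knockout", "rxn": "GABA_UPTAKE",
         "label": "gabP::potE (uptake closed)"}
      ]
    },
    {
      "label": "BLM-1",
      "product": "EX_btl",
      "pathway": "butyrolactam",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"},
        {"type": "fix_flux_multiple", "rxn": "ICD", "factor": 2.0,
         "label": "Ptuf-icd"},
        {"type": "knockout", "rxn": "SUCOAS", "label": "delta-sucCD"},
        {"type": "set_bounds", "rxn": "ACEA", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceA)"},
        {"type": "set_bounds", "rxn": "ACEB", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceB)"}
      ]
    },
    {
      "label": "BLM-2",
      "product": "EX_btl",
      "pathway": "butyrolactam",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"},
        {"type": "fix_flux_multiple", "rxn": "ICD", "factor": 2.0,
         "label": "Ptuf-icd"},
        {"type": "knockout", "rxn": "SUCOAS", "label": "delta-sucCD"},
        {"type": "set_bounds", "rxn": "ACEA", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceA)"},
        {"type": "set_bounds", "rxn": "ACEB", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceB)"},
        {"type": "knockout", "rxn": "GABA_SHUNT_T", "label": "delta-gabT"},
        {"type": "knockout", "rxn": "GABA_SHUNT_D", "label": "delta-gabD"}
      ]
    },
    {
      "label": "BLM-3",
      "product": "EX_btl",
      "pathway": "butyrolactam",
      "edits": [
        {"type": "fix_flux_multiple", "rxn": "ACN", "factor": 2.0,
         "label": "Ptuf-acn"},
        {"type": "fix_flux_multiple", "rxn": "ICD", "factor": 2.0,
         "label": "Ptuf-icd"},
        {"type": "knockout", "rxn": "SUCOAS", "label": "delta-sucCD"},
        {"type": "set_bounds", "rxn": "ACEA", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceA)"},
        {"type": "set_bounds", "rxn": "ACEB", "lb": 0, "ub": 1000,
         "label": "glyoxylate activation (aceB)"},
        {"type": "knockout", "rxn": "GABA_SHUNT_T", "label": "delta-gabT"},
        {"type": "knockout", "rxn": "GABA_SHUNT_D", "label": "delta-gabD"},
        {"type": "knockout", "rxn": "GABA_UPTAKE",
         "label": "gabP::potE (uptake closed)"}
      ]
    }
  ]
}
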