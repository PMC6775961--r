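{
  "description": "Atom-resolved carbon map of nucleotide biosynthesis in methylotrophic methanogens. Carbon enters as the methyl group of methanol (via methyl-H4SPT) or as dissolved inorganic carbon (DIC). Atom indices are 1-based. Atom order per compound is given in each note.",
  "sources": ["MEOH", "DIC"],
  "compounds": [
    {"name": "ch3_h4spt", "n_carbons": 1},
    {"name": "formyl_h4spt", "n_carbons": 1},
    {"name": "acetyl_coa", "n_carbons": 2},
    {"name": "pyruvate", "n_carbons": 3},
    {"name": "glyceraldehyde_3_phosphate", "n_carbons": 3},
    {"name": "dihydroxyacetone_phosphate", "n_carbons": 3},
    {"name": "fructose_6_phosphate", "n_carbons": 6},
    {"name": "ribulose_5_phosphate", "n_carbons": 5},
    {"name": "ribose_5_phosphate", "n_carbons": 5},
    {"name": "serine", "n_carbons": 3},
    {"name": "glycine", "n_carbons": 2},
    {"name": "oxaloacetate", "n_carbons": 4},
    {"name": "aspartate", "n_carbons": 4},
    {"name": "carbamoyl_phosphate", "n_carbons": 1},
    {"name": "pyrimidine_base", "n_carbons": 4},
    {"name": "purine_base", "n_carbons": 5}
  ],
  "reactions": [
    {
      "product": "ch3_h4spt",
      "assignments": ["MEOH"],
      "note": "Methanol methyl transferred to tetrahydrosarcinapterin by the MtaABC methyltransferase system; one carbon, methanol-derived."
    },
    {
      "product": "formyl_h4spt",
      "assignments": [["ch3_h4spt", 1]],
      "note": "Oxidative branch of methylotrophic methanogenesis: methyl-H4SPT oxidized via methylene and methenyl to formyl-H4SPT; the carbon stays methanol-derived. Formyl units for purine C2/C8 are taken from this pool."
    },
    {
      "product": "acetyl_coa",
      "assignments": [["ch3_h4spt", 1], "DIC"],
      "note": "CODH/ACS condensation. Atom 1 = methyl (from methyl-H4SPT), atom 2 = carbonyl (from CO2). Carrier carbons of CoA are not counted."
    },
    {
      "product": "pyruvate",
      "assignments": ["DIC", ["acetyl_coa", 2], ["acetyl_coa", 1]],
      "note": "Reductive carboxylation by pyruvate:ferredoxin oxidoreductase. Atom order C1 carboxyl (new CO2), C2 carbonyl (acetyl carbonyl), C3 methyl (acetyl methyl)."
    },
    {
      "product": "glyceraldehyde_3_phosphate",
      "assignments": [["pyruvate", 1], ["pyruvate", 2], ["pyruvate", 3]],
      "note": "Gluconeogenesis pyruvate -> PEP -> 3-PG -> GAP preserves the carbon skeleton. Atom order C1 aldehyde, C2, C3 phosphomethylene."
    },
    {
      "product": "dihydroxyacetone_phosphate",
      "assignments": [["glyceraldehyde_3_phosphate", 3], ["glyceraldehyde_3_phosphate", 2], ["glyceraldehyde_3_phosphate", 1]],
      "note": "Triosephosphate isomerase; the phosphate-bearing carbon is shared, so GAP C3 maps to DHAP C1. Atom order C1 phosphomethylene, C2 keto, C3 hydroxymethyl."
    },
    {
      "product": "fructose_6_phosphate",
      "assignments": [["dihydroxyacetone_phosphate", 1], ["dihydroxyacetone_phosphate", 2], ["dihydroxyacetone_phosphate", 3], ["glyceraldehyde_3_phosphate", 1], ["glyceraldehyde_3_phosphate", 2], ["glyceraldehyde_3_phosphate", 3]],
      "note": "Aldolase condensation then FBPase: fructose C1-C3 from DHAP C1-C3, C4-C6 from GAP C1-C3."
    },
    {
      "product": "ribulose_5_phosphate",
      "assignments": [["fructose_6_phosphate", 2], ["fructose_6_phosphate", 3], ["fructose_6_phosphate", 4], ["fructose_6_phosphate", 5], ["fructose_6_phosphate", 6]],
      "lost": [["fructose_6_phosphate", 1]],
      "note": "Reverse ribulose-monophosphate route: hexulose-6-phosphate cleaved to ribulose-5-phosphate plus formaldehyde; fructose C1 (methanol-derived) leaves as the formaldehyde carbon."
    },
    {
      "product": "ribose_5_phosphate",
      "assignments": [["ribulose_5_phosphate", 1], ["ribulose_5_phosphate", 2], ["ribulose_5_phosphate", 3], ["ribulose_5_phosphate", 4], ["ribulose_5_phosphate", 5]],
      "note": "Phosphoriboisomerase; skeleton unchanged. Exactly one of the five carbons (C5, ex fructose C6) is methanol-derived."
    },
    {
      "product": "serine",
      "assignments": [["glyceraldehyde_3_phosphate", 1], ["glyceraldehyde_3_phosphate", 2], ["glyceraldehyde_3_phosphate", 3]],
      "note": "Phosphorylated serine pathway from 3-phosphoglycerate (same skeleton as GAP). Atom order C1 carboxyl, C2 alpha, C3 hydroxymethyl."
    },
    {
      "product": "glycine",
      "assignments": [["serine", 1], ["serine", 2]],
      "lost": [["serine", 3]],
      "note": "Serine hydroxymethyltransferase; serine C3 leaves to the methylene-carrier pool. Atom order C1 carboxyl, C2 alpha."
    },
    {
      "product": "oxaloacetate",
      "assignments": [["pyruvate", 1], ["pyruvate", 2], ["pyruvate", 3], "DIC"],
      "note": "Pyruvate carboxylation; C4 is the newly fixed CO2. Atom order C1-C3 as pyruvate, C4 beta-carboxyl."
    },
    {
      "product": "aspartate",
      "assignments": [["oxaloacetate", 1], ["oxaloacetate", 2], ["oxaloacetate", 3], ["oxaloacetate", 4]],
      "note": "Transamination preserves the carbon skeleton. Atom order C1 alpha-carboxyl, C2 alpha, C3 beta, C4 beta-carboxyl."
    },
    {
      "product": "carbamoyl_phosphate",
      "assignments": ["DIC"],
      "note": "Carbamoyl phosphate synthetase fixes bicarbonate directly."
    },
    {
      "product": "pyrimidine_base",
      "assignments": [["carbamoyl_phosphate", 1], ["aspartate", 4], ["aspartate", 3], ["aspartate", 2]],
      "lost": [["aspartate", 1]],
      "note": "Ring atom order C2, C4, C5, C6. C2 from carbamoyl phosphate; C4/C5/C6 from aspartate C4/C3/C2; the aspartate alpha-carboxyl is lost as CO2 on OMP decarboxylation. One of four ring carbons (C5) is methanol-derived."
    },
    {
      "product": "purine_base",
      "assignments": [["formyl_h4spt", 1], ["glycine", 1], ["glycine", 2], "DIC", ["formyl_h4spt", 1]],
      "note": "Ring atom order C2, C4, C5, C6, C8. C4/C5 from glycine, C6 from CO2, C2 and C8 from two formyl units drawn from the methanol-fed one-carbon pool; two of five ring carbons are methanol-derived."
    }
  ]
}
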