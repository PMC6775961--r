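{
  "description": "Atom-resolved carbon map of archaeal isoprenoid lipid biosynthesis (mevalonate pathway) in methylotrophic methanogens. Carbon enters as the methanol methyl group (via methyl-H4SPT) or as DIC. Atom indices are 1-based; atom order per compound is given in each note.",
  "sources": ["MEOH", "DIC"],
  "compounds": [
    {"name": "ch3_h4spt", "n_carbons": 1},
    {"name": "acetyl_coa", "n_carbons": 2},
    {"name": "acetoacetyl_coa", "n_carbons": 4},
    {"name": "hmg_coa", "n_carbons": 6},
    {"name": "mevalonate", "n_carbons": 6},
    {"name": "mevalonate_5_phosphate", "n_carbons": 6},
    {"name": "ipp", "n_carbons": 5},
    {"name": "dmapp", "n_carbons": 5},
    {"name": "geranyl_diphosphate", "n_carbons": 10},
    {"name": "farnesyl_diphosphate", "n_carbons": 15},
    {"name": "geranylgeranyl_diphosphate", "n_carbons": 20},
    {"name": "phytanyl_chain", "n_carbons": 20}
  ],
  "reactions": [
    {
      "product": "ch3_h4spt",
      "assignments": ["MEOH"],
      "note": "Methanol methyl transferred to tetrahydrosarcinapterin; one carbon, methanol-derived."
    },
    {
      "product": "acetyl_coa",
      "assignments": [["ch3_h4spt", 1], "DIC"],
      "note": "CODH/ACS condensation. Atom 1 = methyl (methanol-derived), atom 2 = carbonyl (CO2-derived). CoA carbons not counted."
    },
    {
      "product": "acetoacetyl_coa",
      "assignments": [["acetyl_coa", 2], ["acetyl_coa", 1], ["acetyl_coa", 2], ["acetyl_coa", 1]],
      "note": "Thiolase condensation of two acetyl-CoA. Atom order C1 thioester carbonyl, C2 methylene, C3 keto, C4 methyl; two full acetyl units consumed."
    },
    {
      "product": "hmg_coa",
      "assignments": [["acetoacetyl_coa", 1], ["acetoacetyl_coa", 2], ["acetoacetyl_coa", 3], ["acetoacetyl_coa", 4], ["acetyl_coa", 1], ["acetyl_coa", 2]],
      "note": "HMG-CoA synthase: a third acetyl-CoA attacks the C3 keto group; its methyl becomes the acetate arm methylene (atom 5) and its carbonyl the free carboxylate (atom 6). Atom order C1 thioester, C2, C3, C3-methyl, arm CH2, arm COOH."
    },
    {
      "product": "mevalonate",
      "assignments": [["hmg_coa", 1], ["hmg_coa", 2], ["hmg_coa", 3], ["hmg_coa", 4], ["hmg_coa", 5], ["hmg_coa", 6]],
      "note": "HMG-CoA reductase: thioester carbon (atom 1) reduced to the C5 alcohol of mevalonate; skeleton unchanged."
    },
    {
      "product": "mevalonate_5_phosphate",
      "assignments": [["mevalonate", 1], ["mevalonate", 2], ["mevalonate", 3], ["mevalonate", 4], ["mevalonate", 5], ["mevalonate", 6]],
      "note": "Mevalonate kinase; skeleton unchanged."
    },
    {
      "product": "ipp",
      "assignments": [["mevalonate_5_phosphate", 1], ["mevalonate_5_phosphate", 2], ["mevalonate_5_phosphate", 3], ["mevalonate_5_phosphate", 4], ["mevalonate_5_phosphate", 5]],
      "lost": [["mevalonate_5_phosphate", 6]],
      "note": "Archaeal route: mevalonate-5-phosphate decarboxylated to isopentenyl phosphate then phosphorylated to IPP; the carboxyl (atom 6, CO2-derived) is lost. Three of five IPP carbons are methanol-derived."
    },
    {
      "product": "dmapp",
      "assignments": [["ipp", 1], ["ipp", 2], ["ipp", 3], ["ipp", 4], ["ipp", 5]],
      "note": "IPP isomerase; skeleton unchanged."
    },
    {
      "product": "geranyl_diphosphate",
      "assignments": [["dmapp", 1], ["dmapp", 2], ["dmapp", 3], ["dmapp", 4], ["dmapp", 5], ["ipp", 1], ["ipp", 2], ["ipp", 3], ["ipp", 4], ["ipp", 5]],
      "note": "Head-to-tail prenyl condensation (C10)."
    },
    {
      "product": "farnesyl_diphosphate",
      "assignments": [["geranyl_diphosphate", 1], ["geranyl_diphosphate", 2], ["geranyl_diphosphate", 3], ["geranyl_diphosphate", 4], ["geranyl_diphosphate", 5], ["geranyl_diphosphate", 6], ["geranyl_diphosphate", 7], ["geranyl_diphosphate", 8], ["geranyl_diphosphate", 9], ["geranyl_diphosphate", 10], ["ipp", 1], ["ipp", 2], ["ipp", 3], ["ipp", 4], ["ipp", 5]],
      "note": "Prenyl elongation (C15)."
    },
    {
      "product": "geranylgeranyl_diphosphate",
      "assignments": [["farnesyl_diphosphate", 1], ["farnesyl_diphosphate", 2], ["farnesyl_diphosphate", 3], ["farnesyl_diphosphate", 4], ["farnesyl_diphosphate", 5], ["farnesyl_diphosphate", 6], ["farnesyl_diphosphate", 7], ["farnesyl_diphosphate", 8], ["farnesyl_diphosphate", 9], ["farnesyl_diphosphate", 10], ["farnesyl_diphosphate", 11], ["farnesyl_diphosphate", 12], ["farnesyl_diphosphate", 13], ["farnesyl_diphosphate", 14], ["farnesyl_diphosphate", 15], ["ipp", 1], ["ipp", 2], ["ipp", 3], ["ipp", 4], ["ipp", 5]],
      "note": "Prenyl elongation (C20); 12 of 20 carbons (60%) methanol-derived."
    },
    {
      "product": "phytanyl_chain",
      "assignments": [["geranylgeranyl_diphosphate", 1], ["geranylgeranyl_diphosphate", 2], ["geranylgeranyl_diphosphate", 3], ["geranylgeranyl_diphosphate", 4], ["geranylgeranyl_diphosphate", 5], ["geranylgeranyl_diphosphate", 6], ["geranylgeranyl_diphosphate", 7], ["geranylgeranyl_diphosphate", 8], ["geranylgeranyl_diphosphate", 9], ["geranylgeranyl_diphosphate", 10], ["geranylgeranyl_diphosphate", 11], ["geranylgeranyl_diphosphate", 12], ["geranylgeranyl_diphosphate", 13], ["geranylgeranyl_diphosphate", 14], ["geranylgeranyl_diphosphate", 15], ["geranylgeranyl_diphosphate", 16], ["geranylgeranyl_diphosphate", 17], ["geranylgeranyl_diphosphate", 18], ["geranylgeranyl_diphosphate", 19], ["geranylgeranyl_diphosphate", 20]],
      "note": "Saturation of the GGPP-derived side chain after ether bond formation; the phytane/phytene moieties released by ether cleavage of archaeol and hydroxyarchaeol carry these carbons. Glycerol backbone carbons are not counted (side chains are what is measured)."
    }
  ]
}
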