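{
  "descriptors": ["BalabanJ", "Chi0", "Chi0n", "Chi0v", "Chi1", "Chi1n", "Chi1v", "Chi2n", "Chi2v", "Chi3n", "Chi3v", "Chi4n", "Chi4v", "EccentricConnectivityIndex", "FpDensityMorgan1", "FpDensityMorgan2", "FpDensityMorgan3", "FractionCSP3", "HallKierAlpha", "HeavyAtomCount", "HeavyAtomMolWt", "Kappa1", "Kappa2", "Kappa3", "KierFlex", "LabuteASA", "MaxAbsPartialCharge", "MaxPartialCharge", "MolLogP", "MolMR", "MolWt", "NHOHCount", "NOCount", "NumAmideBonds", "NumAromaticAtoms", "NumAromaticCarbocycles", "NumAromaticHeterocycles", "NumAromaticRings", "NumC", "NumCl", "NumDegree1", "NumDegree2", "NumDegree3", "NumDegree4", "NumDoubleBonds", "NumF", "NumH", "NumHAcceptors", "NumHalogens", "NumHDonors", "NumHeteroatoms", "NumN", "NumO", "NumP", "NumRotatableBonds", "NumSingleBonds", "NumTripleBonds", "NumValenceElectrons", "PEOE_VSA1", "PEOE_VSA10", "PEOE_VSA11", "PEOE_VSA12", "PEOE_VSA13", "PEOE_VSA14", "PEOE_VSA2", "PEOE_VSA3", "PEOE_VSA4", "PEOE_VSA6", "PEOE_VSA7", "PEOE_VSA8", "PEOE_VSA9", "SMR_VSA1", "SMR_VSA10", "SMR_VSA2", "SMR_VSA4", "SMR_VSA5", "SMR_VSA7", "SMR_VSA9", "TopoDiameter", "TopoRadius", "TPSA", "WienerIndex", "ZagrebIndex"],
  "n": 83
}
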