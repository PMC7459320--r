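# Property table for the 8 supported solvent/background-electrolyte media.
# Each medium is represented by a single compound; "alcohol" by 1-octanol and
# "R4NX" (tetraalkylammonium halide) by methylammonium chloride. Values are
# standard reference data for the representative compound.
# Columns/units: name, representative_compound, density (g/cm3),
#   molar_mass (g/mol), melting_point (K)
name	representative_compound	density	molar_mass	melting_point
alcohol	1-octanol	0.824	130.23	257.6
dioxane	1,4-dioxane	1.033	88.11	284.95
KCl	potassium chloride	1.984	74.55	1044
KNO3	potassium nitrate	2.109	101.10	607
NaCl	sodium chloride	2.165	58.44	1074
NaClO4	sodium perchlorate	2.499	122.44	741
NaNO3	sodium nitrate	2.257	84.99	581
R4NX	methylammonium chloride	1.23	67.52	505.5
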