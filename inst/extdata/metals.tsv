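# Property table for the 15 supported lanthanide cations.
# Values compiled from standard reference tables of the elements (CRC-handbook-style
# recommended values). Ionic radii are Shannon effective radii for 6-coordination.
# standard_entropy is S0(298 K) of the solid element, J/(mol K).
# Columns/units:
#   symbol (element), charge (e), atomic_number (count), outer_shell_electrons
#   (electrons beyond the Xe core: 4f+5d+6s, count), ionization_energy_1/2/3 (kJ/mol),
#   electron_affinity (kJ/mol; measured or recommended estimate), atomic_radius (pm,
#   metallic), covalent_radius (pm), ionic_radius (pm, Shannon 6-coordinate),
#   electronegativity_pauling (dimensionless), melting_point (K), boiling_point (K),
#   density (g/cm3), standard_entropy (J/mol/K)
symbol	charge	atomic_number	outer_shell_electrons	ionization_energy_1	ionization_energy_2	ionization_energy_3	electron_affinity	atomic_radius	covalent_radius	ionic_radius	electronegativity_pauling	melting_point	boiling_point	density	standard_entropy
Ce	3	58	4	534.4	1050	1949	60.6	181.8	204	101.0	1.12	1068	3716	6.77	72.0
Ce	4	58	4	534.4	1050	1949	60.6	181.8	204	87.0	1.12	1068	3716	6.77	72.0
Pr	3	59	5	527.0	1020	2086	92.8	182.4	203	99.0	1.13	1208	3793	6.77	73.2
Nd	3	60	6	533.1	1040	2130	9.4	181.4	201	98.3	1.14	1297	3347	7.01	71.5
Pm	3	61	7	540.0	1050	2150	12.5	183.4	199	97.0	1.13	1315	3273	7.26	71.6
Sm	3	62	8	544.5	1070	2260	15.6	180.4	198	95.8	1.17	1345	2067	7.52	69.6
Eu	3	63	9	547.1	1085	2404	11.2	208.4	198	94.7	1.20	1099	1802	5.24	77.8
Gd	3	64	10	593.4	1170	1990	20.5	180.4	196	93.8	1.20	1585	3546	7.90	68.1
Tb	3	65	11	565.8	1110	2114	12.6	177.3	194	92.3	1.20	1629	3503	8.23	73.2
Dy	3	66	12	573.0	1130	2200	1.4	178.1	192	91.2	1.22	1680	2840	8.55	75.6
Ho	3	67	13	581.0	1140	2204	32.6	176.2	192	90.1	1.23	1734	2993	8.80	75.3
Er	3	68	14	589.3	1150	2194	30.1	176.1	189	89.0	1.24	1802	3141	9.07	73.2
Tm	3	69	15	596.7	1160	2285	99.3	175.9	190	88.0	1.25	1818	2223	9.32	74.0
Yb	3	70	16	603.4	1174.8	2417	-1.9	193.3	187	86.8	1.10	1097	1469	6.90	59.9
Lu	3	71	17	523.5	1340	2022.3	23.1	173.8	187	86.1	1.27	1925	3675	9.84	51.0
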