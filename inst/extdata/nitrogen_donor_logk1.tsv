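# Out-of-sample validation table: reference AdaBoost predictions versus
# experimental logK1 values for six well-known nitrogen-donor ligands
# (ADPTZ, MePhPTA, Phen, TERPY, Me-BTP, PDAM) complexing trivalent lanthanides.
# Columns: ligand, cation (symbol), charge, logk1_predicted, logk1_experimental
ligand	cation	charge	logk1_predicted	logk1_experimental
ADPTZ	Ce	3	4.82	4.28
ADPTZ	Pr	3	4.76	4.43
ADPTZ	Nd	3	4.82	4.62
ADPTZ	Sm	3	4.82	4.62
ADPTZ	Eu	3	4.69	4.51
ADPTZ	Gd	3	4.69	4.29
ADPTZ	Tb	3	4.76	4.15
ADPTZ	Dy	3	4.69	4.07
ADPTZ	Ho	3	4.69	4.05
ADPTZ	Er	3	4.69	4.10
ADPTZ	Tm	3	4.62	4.23
ADPTZ	Yb	3	4.69	4.30
ADPTZ	Lu	3	4.74	4.40
MePhPTA	Eu	3	6.70	6.95
Phen	Eu	3	4.84	4.23
TERPY	Gd	3	3.85	2.60
TERPY	Lu	3	3.50	2.80
TERPY	Eu	3	4.15	2.40
Me-BTP	Nd	3	3.46	2.90
Me-BTP	Eu	3	3.81	2.90
PDAM	Ce	3	5.94	4.06
PDAM	Pr	3	5.93	4.09
PDAM	Nd	3	6.30	4.09
PDAM	Sm	3	6.32	4.27
PDAM	Eu	3	6.32	4.17
PDAM	Gd	3	6.28	4.30
PDAM	Tb	3	6.26	3.93
PDAM	Dy	3	6.15	4.05
PDAM	Ho	3	4.69	3.89
PDAM	Er	3	4.65	3.84
PDAM	Tm	3	3.76	3.88
PDAM	Yb	3	4.66	4.08
PDAM	Lu	3	4.74	3.80
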