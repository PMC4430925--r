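unit	stratum	n_mutated_lines	n_lines	frequency_pct	per_kbp_pct	avg_cds_length_bp
NOTCH	ALL	14	45	31.111111	4.434625	7015.5
NOTCH_LIGANDS	ALL	0	45	0	0	2901
RAS	ALL	0	45	0	0	570
ERBB	ALL	0	45	0	0	3839.25
PTCH	ALL	0	45	0	0	3978
TP53	ALL	21	45	46.666667	39.481105	1182
APC	ALL	0	45	0	0	8532
PABPN1	ALL	0	45	0	0	921
FPGT	ALL	0	45	0	0	1785
NONO	ALL	0	45	0	0	1416
NOTCH1	ALL	3	45	6.666667	0.869414	7668
NOTCH2	ALL	0	45	0	0	7416
NOTCH3	ALL	6	45	13.333333	1.914059	6966
NOTCH4	ALL	7	45	15.555556	2.587418	6012
JAG1	ALL	0	45	0	0	3657
JAG2	ALL	0	45	0	0	3717
DLL1	ALL	0	45	0	0	2172
DLL4	ALL	0	45	0	0	2058
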