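ligand	fold_change	receptor	delta_lr	delta_sum	n_lrdb
CLU	2.81	LRP2	0.014	1.07	1
FGA	2.74	PLAT	0.035	4.58	1
FGA	2.74	ITGB2	0.029	3.85	3
FGA	2.74	ITGB1	0.021	2.67	4
FGA	2.74	ITGAV	0.016	1.52	2
FGA	2.74	CDH5	-0.005	-2.51	1
FN1	2.01	ITGB2	0.028	3.40	1
FN1	2.01	ITGB1	0.020	2.22	4
FN1	2.01	DPP4	0.017	1.69	4
FN1	2.01	MAG	0.012	1.08	6
FN1	2.01	ITGAV	0.015	1.07	7
FN1	2.01	FLT4	0.000	-1.83	1
FN1	2.01	ITGA6	-0.004	-2.61	5
HPX	1.77	LRP1	0.011	0.22	2
C3	1.65	ITGB2	0.027	3.12	1
C3	1.65	LRP1	0.011	0.12	5
C3	1.65	CFB	0.007	-0.51	6
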