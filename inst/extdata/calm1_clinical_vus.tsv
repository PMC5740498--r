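variant	maf	sd_rmsd	provenance	unrefined	score	dms_call	indication
D94A	NA	0.26	imputed	NA	0.46	Likely damaging	Cardio
D96H	NA	0.26	imputed	NA	0.72	Likely damaging	Cardio
I28V	1e-05	0.05	mild_refinement	0.88	0.88	Uncertain	Cardio
N98S	NA	0.05	mild_refinement	0.89	0.89	Uncertain	Cardio
T35I	4e-06	0.04	mild_refinement	0.93	0.93	Likely benign	Non-Cardio
E48G	NA	0.05	mild_refinement	0.93	0.93	Likely benign	Cardio
G26D	NA	0.06	mild_refinement	0.94	0.94	Likely benign	Non-Cardio
T27S	3e-05	0.05	mild_refinement	0.96	0.96	Likely benign	Non-Cardio
V122A	NA	0.05	mild_refinement	0.98	0.98	Likely benign	Non-Cardio
A104G	NA	0.08	mild_refinement	1	1	Likely benign	Non-Cardio
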