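label	vO2	vs
glucose	3.60	0.60
lactate	3.81	1.17
glucose_lactate	3.73	0.96
oleate	4.11	0.16
glucose_oleate	4.02	0.24
acetate	4.8	2.4
glucose_acetate	4.6	2.11
acetoacetate	3.93	0.98
glucose_acetoacetate	3.81	0.86
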