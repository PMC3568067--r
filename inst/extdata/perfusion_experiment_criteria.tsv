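label	vO2	vs
glucose	4.28	0.55
lactate	4.71	1.41
glucose_lactate	4.70	1.59
oleate	4.94	0.18
glucose_oleate	4.36	0.21
acetate	4.28	1.68
glucose_acetate	4.69	1.46
acetoacetate	4.20	0.53
glucose_acetoacetate	4.95	1.01
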