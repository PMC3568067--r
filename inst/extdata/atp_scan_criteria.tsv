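label	vO2	vs
ole=1.00	4.1101	0.1626
glc=1.00	3.6007	0.6005
aca=1.00	3.9269	0.9806
lac=1.00	3.8124	1.2701
glc=0.79,ole=0.21	3.8534	0.3823
glc=0.42,ole=0.37,aca=0.09,lac=0.12	3.9830	0.3154
glc=0.33,ole=0.19,aca=0.43,lac=0.05	3.9420	0.4536
glc=0.20,ole=0.16,aca=0.26,lac=0.38	3.9485	0.5292
glc=0.46,ole=0.03,aca=0.46,lac=0.05	3.7757	0.6847
glc=0.17,ole=0.09,aca=0.01,lac=0.73	3.8880	0.7020
glc=0.20,ole=0.04,aca=0.41,lac=0.35	3.8534	0.7841
glc=0.16,ole=0.03,aca=0.33,lac=0.48	3.8448	0.8575
glc=0.06,ole=0.05,aca=0.03,lac=0.86	3.8794	0.8942
glc=0.02,ole=0.02,aca=0.52,lac=0.44	3.9010	0.9677
glc=0.07,aca=0.07,lac=0.86	3.7930	1.1556
aca=0.13,lac=0.87	3.8297	1.2247
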