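gene	fg_omega2	prop_2b	lnl_h0	lnl_h1	lr_printed	p_printed	p_adj_printed	n_beb_sites
TMEM132B	3.81581	0.01666	-6438.78	-6419.68	38.20475	6.37e-10	1.18e-06	52
PARP1	4.76894	0.00604	-5357.53	-5341.29	32.48145	1.20e-08	2.22e-05	23
TECTA	3.67139	0.00194	-12076.1	-12060.4	31.42787	2.07e-08	3.83e-05	18
FUBP3	4.89809	0.01916	-4880.95	-4869.76	22.38143	2.24e-06	0.004144	12
IGF2BP1	4.96893	0.00201	-4448.2	-4438.13	20.13898	7.20e-06	0.013321	9
SPEG	4.81594	0.00254	-11218.8	-11209.4	18.85029	1.41e-05	0.026085	13
ADAMTS5	4.38148	0.00124	-4320.48	-4311.43	18.1014	2.09e-05	0.038665	8
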