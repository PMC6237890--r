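gene	fg_omega	lnl_h0	lnl_h1	p_printed	p_adj_printed	max_delta_ssls
VPS45	0.40038	-4037.348759	-3956.06672	3.11e-37	8.3037e-34	7.730292
ABCC10	0.44339	-18216.8972	-18153.02735	1.28e-29	3.4176e-26	8.828157
FASN	0.19743	-40595.23443	-40538.33849	1.45e-26	3.8715e-23	9.661292
DUS3L	0.34814	-8646.525061	-8591.484612	9.41e-26	2.51247e-22	8.224026
DDAH2	0.45032	-2977.374327	-2929.688683	1.58e-22	4.2186e-19	6.582644
SASH1	0.19451	-6515.324513	-6472.937933	3.35e-20	8.9445e-17	6.525431
GPR155	0.57001	-5926.033389	-5888.825926	6.33e-18	1.69011e-14	6.877673
DUSP27	0.28847	-13197.13408	-13162.41783	7.91e-17	2.11197e-13	6.749015
EMILIN3	0.26942	-9364.829765	-9346.305662	1.15e-09	3.0705e-06	8.265838
DCLRE1A	0.70785	-6950.035862	-6931.672364	1.36e-09	3.6312e-06	8.100957
DGKQ	0.1879	-12994.3629	-12976.13466	1.56e-09	4.1652e-06	7.537842
VWF	0.21584	-26711.98598	-26695.2834	7.48e-09	1.99716e-05	8.820315
GUCY2C	0.45014	-6447.80369	-6431.307957	9.26e-09	2.47242e-05	5.926296
ABCD4	0.23237	-6428.830395	-6414.05014	5.42e-08	0.000144714	6.854527
TACC3	0.48752	-7423.970534	-7410.509676	2.12e-07	0.00056604	8.265423
LMTK2	0.34446	-19363.6547	-19351.05935	5.19e-07	0.00138573	8.545421
RIN3	0.27223	-6861.555137	-6849.333436	7.65e-07	0.00204255	5.750655
KCNA5	0.18524	-6876.444906	-6864.677432	1.23e-06	0.0032841	6.664093
TRMT12	0.48457	-6214.487554	-6203.00578	1.65e-06	0.0044055	7.141302
POLL	0.41568	-7373.848752	-7362.382731	1.68e-06	0.0044856	9.073179
ANKRD5	0.3288	-9488.47528	-9477.525821	2.87e-06	0.0076629	9.485991
LAMB2	0.23606	-17812.14129	-17801.84156	5.66e-06	0.0151122	7.663766
IL17RA	0.40977	-10647.044	-10636.87528	6.49e-06	0.0173283	10.242048
TRIML1	0.45219	-4898.490822	-4888.744854	1.01e-05	0.026967	7.674387
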