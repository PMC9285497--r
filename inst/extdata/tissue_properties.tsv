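tissue	density	sigma	specific_heat	thermal_conductivity	perfusion	water_fraction
electrode	6450	1e8	840	18	0	0
plastic	70	1e-5	1045	0.026	0	0
nidus	1046	0.22	2726	0.56	48e-4	0.60
sclerotic	1908	0.0535	1313	0.32	2.95e-4	0.23
trabecular	1178	0.0867	2274	0.31	5.9e-4	0.27
cortical	1908	0.022	1313	0.32	0	0.23
muscle	1090	0.446	3421	0.49	6.7e-4	0.76
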