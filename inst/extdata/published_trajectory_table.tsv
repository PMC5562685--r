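component	network	selected_order	r2	beta_high	ci_low	ci_high	t	df	p
2	anterior dorsal attention	1	0.246	-3.75e-04	-4.31e-04	-3.19e-04	-13.19	534	1.36e-34
3	language-related speech	1	0.139	-3.87e-04	-4.69e-04	-3.05e-04	-9.29	534	3.77e-19
4	cerebellum 1	1	0.025	-9.44e-05	-1.45e-04	-4.41e-05	-3.68	534	2.54e-04
5	cerebellum 2	1	0.028	-1.07e-04	-1.61e-04	-5.36e-05	-3.93	534	9.80e-05
6	ventral default mode	1	0.340	-4.97e-04	-5.56e-04	-4.38e-04	-16.57	534	4.66e-50
7	posterior dorsal attention	1	0.096	-2.29e-04	-2.89e-04	-1.70e-04	-7.52	534	2.40e-13
9	caudate-related	1	0.168	-3.14e-04	-3.73e-04	-2.54e-04	-10.37	534	4.35e-23
11	posterior default mode	1	0.043	-1.46e-04	-2.04e-04	-8.71e-05	-4.88	534	1.41e-06
12	auditory	1	0.306	-4.58e-04	-5.16e-04	-3.99e-04	-15.34	534	2.90e-44
13	thalamus-related	1	0.113	-3.92e-04	-4.85e-04	-2.98e-04	-8.24	534	1.32e-15
14	cerebellum 3	1	0.157	-2.89e-04	-3.45e-04	-2.32e-04	-9.96	534	1.56e-21
15	sensory-motor	1	0.280	-4.96e-04	-5.64e-04	-4.29e-04	-14.41	534	5.44e-40
16	hippocampus-related	1	0.479	-5.67e-04	-6.17e-04	-5.17e-04	-22.17	534	1.11e-77
17	temporal lobe-related	2	0.039	-1.01e-05	-1.44e-05	-5.75e-06	-4.59	533	5.66e-06
19	cerebellum 4	1	0.070	-2.09e-04	-2.73e-04	-1.44e-04	-6.36	534	4.47e-10
20	cerebellum 5	1	0.118	-2.80e-04	-3.45e-04	-2.15e-04	-8.45	534	2.88e-16
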