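sample	gene	ct	group	tissue	timepoint
control_1	Actb	17.98	control	bone	d3
control_1	B2m	20.28	control	bone	d3
control_1	Gapdh	19.6	control	bone	d3
control_1	Hprt	23.07	control	bone	d3
control_1	Ppia	17.96	control	bone	d3
control_2	Actb	16.7	control	bone	d3
control_2	B2m	20.03	control	bone	d3
control_2	Gapdh	18.54	control	bone	d3
control_2	Hprt	22.39	control	bone	d3
control_2	Ppia	17.39	control	bone	d3
control_3	Actb	17.03	control	bone	d3
control_3	B2m	20.21	control	bone	d3
control_3	Gapdh	18.95	control	bone	d3
control_3	Hprt	23.13	control	bone	d3
control_3	Ppia	18.15	control	bone	d3
control_4	Actb	16.66	control	bone	d3
control_4	B2m	19.95	control	bone	d3
control_4	Gapdh	19.36	control	bone	d3
control_4	Hprt	23.39	control	bone	d3
control_4	Ppia	17.89	control	bone	d3
control_5	Actb	17.26	control	bone	d3
control_5	B2m	20.59	control	bone	d3
control_5	Gapdh	19.35	control	bone	d3
control_5	Hprt	23.48	control	bone	d3
control_5	Ppia	18.12	control	bone	d3
control_6	Actb	16.78	control	bone	d3
control_6	B2m	20.16	control	bone	d3
control_6	Gapdh	19.11	control	bone	d3
control_6	Hprt	23.28	control	bone	d3
control_6	Ppia	17.84	control	bone	d3
Fx_1	Actb	19.09	Fx	bone	d3
Fx_1	B2m	20.48	Fx	bone	d3
Fx_1	Gapdh	19.19	Fx	bone	d3
Fx_1	Hprt	23.15	Fx	bone	d3
Fx_1	Ppia	18.27	Fx	bone	d3
Fx_2	Actb	18.68	Fx	bone	d3
Fx_2	B2m	20.05	Fx	bone	d3
Fx_2	Gapdh	18.64	Fx	bone	d3
Fx_2	Hprt	23.53	Fx	bone	d3
Fx_2	Ppia	17.36	Fx	bone	d3
Fx_3	Actb	19.42	Fx	bone	d3
Fx_3	B2m	20.81	Fx	bone	d3
Fx_3	Gapdh	20.06	Fx	bone	d3
Fx_3	Hprt	23.41	Fx	bone	d3
Fx_3	Ppia	18.24	Fx	bone	d3
Fx_4	Actb	18.3	Fx	bone	d3
Fx_4	B2m	20.01	Fx	bone	d3
Fx_4	Gapdh	19.06	Fx	bone	d3
Fx_4	Hprt	23.01	Fx	bone	d3
Fx_4	Ppia	18.04	Fx	bone	d3
Fx_5	Actb	19.04	Fx	bone	d3
Fx_5	B2m	19.49	Fx	bone	d3
Fx_5	Gapdh	19.42	Fx	bone	d3
Fx_5	Hprt	23.26	Fx	bone	d3
Fx_5	Ppia	18.56	Fx	bone	d3
Fx_6	Actb	18.67	Fx	bone	d3
Fx_6	B2m	20.77	Fx	bone	d3
Fx_6	Gapdh	19.65	Fx	bone	d3
Fx_6	Hprt	23.65	Fx	bone	d3
Fx_6	Ppia	18.54	Fx	bone	d3
TBI_1	Actb	16.35	TBI	bone	d3
TBI_1	B2m	19.47	TBI	bone	d3
TBI_1	Gapdh	18.23	TBI	bone	d3
TBI_1	Hprt	22.64	TBI	bone	d3
TBI_1	Ppia	17.58	TBI	bone	d3
TBI_2	Actb	16.66	TBI	bone	d3
TBI_2	B2m	19.97	TBI	bone	d3
TBI_2	Gapdh	19.1	TBI	bone	d3
TBI_2	Hprt	22.95	TBI	bone	d3
TBI_2	Ppia	18.25	TBI	bone	d3
TBI_3	Actb	16.24	TBI	bone	d3
TBI_3	B2m	20.13	TBI	bone	d3
TBI_3	Gapdh	18.89	TBI	bone	d3
TBI_3	Hprt	22.95	TBI	bone	d3
TBI_3	Ppia	18.39	TBI	bone	d3
TBI_4	Actb	17.2	TBI	bone	d3
TBI_4	B2m	20.61	TBI	bone	d3
TBI_4	Gapdh	19.14	TBI	bone	d3
TBI_4	Hprt	23.22	TBI	bone	d3
TBI_4	Ppia	17.86	TBI	bone	d3
TBI_5	Actb	16.98	TBI	bone	d3
TBI_5	B2m	19.7	TBI	bone	d3
TBI_5	Gapdh	19.19	TBI	bone	d3
TBI_5	Hprt	22.77	TBI	bone	d3
TBI_5	Ppia	17.88	TBI	bone	d3
TBI_6	Actb	16.09	TBI	bone	d3
TBI_6	B2m	19.59	TBI	bone	d3
TBI_6	Gapdh	18.45	TBI	bone	d3
TBI_6	Hprt	22.05	TBI	bone	d3
TBI_6	Ppia	17.56	TBI	bone	d3
TBI+Fx_1	Actb	18	TBI+Fx	bone	d3
TBI+Fx_1	B2m	19.37	TBI+Fx	bone	d3
TBI+Fx_1	Gapdh	18.69	TBI+Fx	bone	d3
TBI+Fx_1	Hprt	21.77	TBI+Fx	bone	d3
TBI+Fx_1	Ppia	17.13	TBI+Fx	bone	d3
TBI+Fx_2	Actb	18.68	TBI+Fx	bone	d3
TBI+Fx_2	B2m	20.71	TBI+Fx	bone	d3
TBI+Fx_2	Gapdh	19.25	TBI+Fx	bone	d3
TBI+Fx_2	Hprt	23.28	TBI+Fx	bone	d3
TBI+Fx_2	Ppia	18.38	TBI+Fx	bone	d3
TBI+Fx_3	Actb	18	TBI+Fx	bone	d3
TBI+Fx_3	B2m	20.18	TBI+Fx	bone	d3
TBI+Fx_3	Gapdh	19.1	TBI+Fx	bone	d3
TBI+Fx_3	Hprt	22.75	TBI+Fx	bone	d3
TBI+Fx_3	Ppia	17.88	TBI+Fx	bone	d3
TBI+Fx_4	Actb	18.1	TBI+Fx	bone	d3
TBI+Fx_4	B2m	19.68	TBI+Fx	bone	d3
TBI+Fx_4	Gapdh	18.88	TBI+Fx	bone	d3
TBI+Fx_4	Hprt	23.28	TBI+Fx	bone	d3
TBI+Fx_4	Ppia	17.2	TBI+Fx	bone	d3
TBI+Fx_5	Actb	18.21	TBI+Fx	bone	d3
TBI+Fx_5	B2m	19.64	TBI+Fx	bone	d3
TBI+Fx_5	Gapdh	18.62	TBI+Fx	bone	d3
TBI+Fx_5	Hprt	22.54	TBI+Fx	bone	d3
TBI+Fx_5	Ppia	17.82	TBI+Fx	bone	d3
TBI+Fx_6	Actb	19.3	TBI+Fx	bone	d3
TBI+Fx_6	B2m	20.34	TBI+Fx	bone	d3
TBI+Fx_6	Gapdh	19.11	TBI+Fx	bone	d3
TBI+Fx_6	Hprt	23.41	TBI+Fx	bone	d3
TBI+Fx_6	Ppia	18.36	TBI+Fx	bone	d3
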