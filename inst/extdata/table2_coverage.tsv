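sample	shared_pct	shared_n	other_pct	other_n	pentosus_pct	sunkii_pct
S01	98.73	13	0.03	3	1.24	0.01
S02	95.06	12	0.09	6	4.83	0.02
S03	91.16	14	0.36	6	8.47	NA
S04	44.69	14	0.44	11	36.27	18.6
S05	90.24	13	0.07	4	6.33	3.36
S06	98.62	12	0.01	5	1.37	NA
S07	92.47	12	0.01	1	7.52	NA
S08	99.93	10	0.02	3	0.05	NA
S09	98.89	12	0.11	3	1.00	NA
S10	99.91	7	0.09	1	NA	NA
S11	94.59	15	0.05	3	5.36	NA
S12	99.31	13	0.09	5	0.33	0.27
S13	94.06	12	0.14	4	5.81	NA
S14	94.76	13	0.23	5	5.01	NA
S15	99.26	10	0.03	5	0.71	NA
S16	98.11	11	0.02	4	1.86	NA
S17	89.88	11	0.04	2	10.08	NA
S18	99.5	11	0.18	3	0.31	NA
S19	95.44	14	0.13	6	4.43	NA
S20	98.24	10	0.63	5	1.12	0.01
S21	97.85	13	0.03	7	2.11	NA
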