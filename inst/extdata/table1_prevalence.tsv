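species	qpcr_count	qpcr_avg_pct	qpcr_sd	ngs_count	ngs_avg_pct	ngs_sd
Lacticaseibacillus paracasei	21	8.26	10.59	21	6.34	9.10
Lactococcus lactis	21	32.79	18.17	21	37.18	20.40
Streptococcus thermophilus	20	42.03	25.51	21	42.24	28.20
Lactiplantibacillus plantarum	20	12.00	14.76	20	3.47	6.56
Loigolactobacillus coryniformis	19	0.60	0.95	19	0.42	0.62
Lentilactobacillus parabuchneri	18	4.96	9.28	20	2.68	6.27
Latilactobacillus curvatus	18	0.77	0.85	19	0.26	0.30
Lactobacillus helveticus	5	3.28	2.48	21	0.63	1.47
Leuconostoc mesenteroides	9	0.31	0.22	14	0.13	0.15
Lactobacillus delbrueckii	4	1.58	1.54	19	0.66	1.89
Levilactobacillus brevis	7	0.47	0.61	16	0.26	0.55
Latilactobacillus sakei	10	0.24	0.25	12	0.10	0.12
Pediococcus pentosaceus	13	0.41	0.43	9	0.03	0.03
Lactiplantibacillus pentosus	0	NA	NA	20	5.21	7.91
Lacticaseibacillus rhamnosus	5	0.24	0.36	13	0.05	0.14
Enterococcus gilvus	0	NA	NA	15	0.03	0.05
Lactiplantibacillus paraplantarum	13	0.38	0.42	0	NA	NA
Lentilactobacillus sunkii	0	NA	NA	10	2.23	5.85
Streptococcus uberis	0	NA	NA	10	0.01	0.01
Latilactobacillus fuchuensis	0	NA	NA	9	0.02	0.02
Enterococcus faecalis	1	0.11	NA	7	0.00	0.00
Paucilactobacillus nenjiangensis	0	NA	NA	8	0.14	0.20
Other species	0	NA	NA	20	0.05	0.06
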