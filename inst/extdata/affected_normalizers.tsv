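name	level	specimen	relative_change	study_ref
Actb	protein	Hippocampus BD	CA1 +1.19; CA2/3 -1.3; DG -1.225	ref44
Tubb	protein	Hippocampus BD	CA1 -1.14; CA2/3 -1.19; DG -1.11	ref44
Actb	protein	Hippocampus SCZ	CA1 +1.1; CA2 NS; DG -1.176	ref44
Tubb	protein	Hippocampus SCZ	CA1 -1.08; CA2 -1.09; DG -1.1	ref44
Tuba	protein	ACC MDD	+1.81	ref42
Tubb	protein	ACC BD	-1.35	ref42
Actb	protein	DPC BD	-1.46	ref43
Tubb	protein	DPC BD	-1.12	ref43
Tuba	protein	DPC SCZ	+1.3	ref43
Tubb	protein	DPC SCZ	+1.42	ref43
Actb	mRNA	Lithium-treated mice, brain	+7.479	ref18
Tubb	mRNA	Lithium-treated rats, PFC synaptosomes	-0.48	ref48
Gapdh	mRNA	Lithium-treated rats, PFC synaptosomes	downregulated	ref48
Gapdh	protein	Lithium-treated rats, PFC	-1.27	ref50
Actb	protein	Lithium-treated rats, IMCD	+1.7	ref49
Tuba4	mRNA	Lithium-treated mice, brain	+1.3	ref17
Tuba	mRNA	Lithium-treated rats, brain	+2.2	ref46
Actb	protein	Ischemia, mouse brain synaptosomes	+1.6	ref51
Gapdh	protein	Ischemia, mouse brain synaptosomes	+2.4	ref51
Tubb3	protein	Lithium-treated mice, FC	+1.07	unpublished
Tubb4	protein	Lithium-treated mice, FC	+1.05	unpublished
Tubb5	protein	Lithium-treated mice, FC	+1.04	unpublished
Actb	mRNA	Lithium-treated mice, FC	-1.11	ref16
Tuba8	mRNA	Lithium-treated mice, FC	+1.67	ref16
Tubb2a	mRNA	Lithium-treated mice, FC	+1.24	ref16
Tubb2c	mRNA	Lithium-treated mice, FC	+1.17	ref16
Tuba1a	mRNA	Lithium-treated mice, FC	+1.12	ref16
Tuba1b	mRNA	Lithium-treated mice, FC	+1.06	ref16
Tuba4a	mRNA	Lithium-treated mice, FC	+1.2	ref16
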