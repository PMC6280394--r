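gene	position_a	position_b	ref_a	rate_a	ref_b	rate_b	codon_before	codon_after	gene_class	section
nad5	1580	1580	T	NA	C	0.97	TCA	TTA	intact	loss
ccmB	28	28	T	NA	C	0.91	CAT	TAT	intact	loss
ccmFc	1145	1145	T	NA	C	0.96	CCA	CTA	intact	loss
atp6_partial	839	839	T	NA	C	0.96	ACA	ATA	chimeric	loss
ccmC	584	584	C	0.14	C	NA	ACC	ATC	intact	new
cox2	786	786	C	0.16	C	NA	ACC	ACT	intact	new
cox3	225	225	C	0.15	C	NA	ACC	ACT	intact	new
atp1	555	555	C	0.18	C	NA	ATC	ATT	intact	new
nad7	926	926	C	0.87	C	0.09	TCA	TTA	intact	large
mttB	25	25	C	0.17	C	0.96	CTG	TTG	intact	large
mttB	373	373	C	0.26	C	0.96	CTT	TTT	intact	large
mttB	527	527	C	0.02	C	0.85	TCG	TTG	intact	large
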