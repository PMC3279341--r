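id	name	pattern
PS00001	N_glycosylation	N-{P}-[ST]-{P}
PS00005	PKC_phospho_site	[ST]-x-[RK]
PS00006	CK2_phospho_site	[ST]-x(2)-[DE]
PS00007	Tyr_kinase_phospho_site	[RK]-x(2,3)-[DE]-x(2,3)-Y
PS00008	N_myristoylation	G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}
PS00009	Amidation	x-G-[RK]-[RK]
PS00342	Microbody_C_terminal	[STAGCN]-[RKH]-[LIVMAFY]>
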