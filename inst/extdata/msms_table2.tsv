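observed	calculated	cleavage	description	qtrap_only	in_catalog
78.9589	78.9585	g & i	P - H3O	FALSE	TRUE
152.9959	152.9953	h	P-Gro - H3O	FALSE	TRUE
171.0062	171.0059	g	P-Gro - H	FALSE	TRUE
241.2171	241.2169	b1 or b2	(15:0) FA - H	FALSE	TRUE
315.0463	315.0481	f	Glc-P-Gro - H3O	FALSE	TRUE
477.1002	477.1010	d	Glc-Glc-P-Gro - H3O	FALSE	TRUE
701.3100	701.3051	b1 & j	(15:0) MAG-Glc-Glc-P - H3O	FALSE	TRUE
719.3195	719.3257	a1 & j	(15:0) MAG-Glc-Glc-P - H	FALSE	TRUE
775.3502	775.3519	b1	(15:0) lyso-form - H3O	FALSE	TRUE
793.3617	793.3625	a1	(15:0) lyso-form - H	FALSE	TRUE
943.5303	943.5399	j	DAG-Glc-Glc-P - H	FALSE	TRUE
1017.5769	1017.5770	M	(30:0) LTAP - H	FALSE	TRUE
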