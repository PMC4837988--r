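observed	calculated	cleavage	description	qtrap_only	in_catalog
299.2568	299.2588	a1 & c	(15:0) MAG - OH	FALSE	TRUE
327.2885	327.2901	a2 & c	(17:0) MAG - OH	FALSE	TRUE
347.0944	347.0955	d	Glc-Glc - H2O + Na+	FALSE	TRUE
365.1056	365.1060	c	Glc-Glc + Na+	FALSE	TRUE
405.1360	405.1374	b1 & b2	CH2=CH-CH2-Glc-Glc + Na+	FALSE	TRUE
483.2907	483.2936	b1 & f	(15:0) MAG-Glc - H2O + Na+	FALSE	TRUE
511.3233	511.3249	b2 & f	(17:0) MAG-Glc - H2O + Na+	FALSE	TRUE
645.3448	645.3464	b1	(15:0) MAG-Glc-Glc - H2O + Na+	FALSE	TRUE
673.3760	673.3777	b2	(17:0) MAG-Glc-Glc - H2O + Na+	FALSE	TRUE
753.5487	753.5496	f	(32:0) DAG-Glc + Na+	FALSE	TRUE
915.6005	915.6025	M	(32:0) DAG-Glc-Glc + Na+	FALSE	TRUE
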