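##gff-version 3
scaffold_1	demo	gene	100	200	.	+	.	ID=g1;role=housekeeping
scaffold_1	demo	gene	400	1200	.	-	.	ID=g2;role=backbone_nrps
scaffold_1	demo	gene	1300	1800	.	+	.	ID=g3;role=tailoring
scaffold_1	demo	gene	2100	2600	.	+	.	ID=g4;role=racemase
scaffold_1	demo	gene	3000	3400	.	-	.	ID=g5;role=housekeeping
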