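##gff-version 3
chr1	imprintr	gene	1	1500	.	+	.	ID=gene00001
chr1	imprintr	gene	2001	3500	.	+	.	ID=gene00002
chr1	imprintr	gene	4001	5500	.	+	.	ID=gene00003
chr1	imprintr	gene	6001	7500	.	+	.	ID=gene00004
chr1	imprintr	gene	8001	9500	.	+	.	ID=gene00005
chr1	imprintr	gene	10001	11500	.	+	.	ID=gene00006
chr1	imprintr	gene	12001	13500	.	+	.	ID=gene00007
chr1	imprintr	gene	14001	15500	.	+	.	ID=gene00008
chr1	imprintr	gene	16001	17500	.	+	.	ID=gene00009
chr1	imprintr	gene	18001	19500	.	+	.	ID=gene00010
chr2	imprintr	gene	1	1500	.	+	.	ID=gene00011
chr2	imprintr	gene	2001	3500	.	+	.	ID=gene00012
chr2	imprintr	gene	4001	5500	.	+	.	ID=gene00013
chr2	imprintr	gene	6001	7500	.	+	.	ID=gene00014
chr2	imprintr	gene	8001	9500	.	+	.	ID=gene00015
chr2	imprintr	gene	10001	11500	.	+	.	ID=gene00016
chr2	imprintr	gene	12001	13500	.	+	.	ID=gene00017
chr2	imprintr	gene	14001	15500	.	+	.	ID=gene00018
chr2	imprintr	gene	16001	17500	.	+	.	ID=gene00019
chr2	imprintr	gene	18001	19500	.	+	.	ID=gene00020
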