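##fileformat=VCFv4.2
##source=imprintr simulate (seed=42)
##contig=<ID=chr1>
##contig=<ID=chr2>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P1	P2
chr1	40	.	T	A	78.4	PASS	DP=51	GT	1/1	0/0
chr1	89	.	G	T	40.3	PASS	DP=35	GT	1/1	0/1
chr1	801	.	C	G	42.1	PASS	DP=43	GT	1/1	0/1
chr1	1178	.	G	C	43.6	PASS	DP=33	GT	0/0	0/1
chr1	1190	.	A	T	86.1	PASS	DP=44	GT	1/1	0/0
chr1	1456	.	T	C	74.8	PASS	DP=49	GT	1/1	0/1
chr1	2935	.	A	C	40.2	PASS	DP=47	GT	0/1	1/1
chr1	3365	.	C	A	68.5	PASS	DP=44	GT	1/1	0/0
chr1	3438	.	T	A	82.3	PASS	DP=41	GT	1/1	1/1
chr1	3464	.	A	C	59.7	PASS	DP=39	GT	1/1	0/0
chr1	4300	.	T	A	62.8	PASS	DP=31	GT	0/1	0/0
chr1	6169	.	A	T	36.2	PASS	DP=42	GT	0/1	1/1
chr1	6323	.	A	C	89.5	PASS	DP=38	GT	0/0	0/1
chr1	6891	.	C	G	30.3	PASS	DP=39	GT	0/0	0/1
chr1	6918	.	G	A	82.9	PASS	DP=43	GT	0/0	0/1
chr1	7429	.	A	G	33.2	PASS	DP=36	GT	0/1	0/0
chr1	8074	.	G	T	66.4	PASS	DP=50	GT	0/0	0/1
chr1	8261	.	T	C	81.5	PASS	DP=37	GT	0/1	0/1
chr1	9258	.	A	C	46.7	PASS	DP=46	GT	0/1	0/0
chr1	9400	.	A	C	65.1	PASS	DP=42	GT	0/1	0/1
chr1	10542	.	A	G	38.2	PASS	DP=47	GT	0/1	0/0
chr1	10888	.	C	T	72.6	PASS	DP=36	GT	0/1	0/1
chr1	11208	.	G	A	44.4	PASS	DP=47	GT	0/0	1/1
chr1	11373	.	C	T	45.9	PASS	DP=35	GT	0/1	1/1
chr1	13220	.	A	G	67.3	PASS	DP=34	GT	0/0	0/1
chr1	14069	.	G	A	68.4	PASS	DP=36	GT	0/0	1/1
chr1	14346	.	T	A	80.0	PASS	DP=35	GT	0/1	0/1
chr1	14447	.	T	C	75.8	PASS	DP=51	GT	0/0	1/1
chr1	14494	.	A	T	55.7	PASS	DP=45	GT	0/0	0/0
chr1	14550	.	G	C	83.3	PASS	DP=47	GT	0/0	1/1
chr1	14706	.	T	C	66.7	PASS	DP=46	GT	0/1	1/1
chr1	14732	.	C	T	51.2	PASS	DP=36	GT	0/0	1/1
chr1	15456	.	A	C	68.7	PASS	DP=40	GT	0/0	1/1
chr1	16088	.	G	A	72.2	PASS	DP=39	GT	1/1	0/1
chr1	16090	.	C	A	82.2	PASS	DP=35	GT	0/1	0/1
chr1	16336	.	G	A	53.5	PASS	DP=39	GT	0/1	0/0
chr1	16345	.	G	A	49.0	PASS	DP=36	GT	0/0	1/1
chr1	16473	.	T	C	37.0	PASS	DP=45	GT	1/1	1/1
chr1	17276	.	G	C	70.2	PASS	DP=39	GT	1/1	0/0
chr1	17346	.	G	A	43.8	PASS	DP=40	GT	0/1	0/1
chr1	17407	.	T	G	44.5	PASS	DP=47	GT	0/0	1/1
chr1	18196	.	G	T	87.8	PASS	DP=30	GT	1/1	1/1
chr1	18657	.	C	G	48.8	PASS	DP=33	GT	0/0	1/1
chr2	296	.	T	C	61.0	PASS	DP=36	GT	0/0	1/1
chr2	435	.	A	T	59.8	PASS	DP=43	GT	0/0	0/1
chr2	672	.	T	C	58.2	PASS	DP=40	GT	0/0	1/1
chr2	835	.	G	C	37.3	PASS	DP=38	GT	1/1	1/1
chr2	2430	.	C	T	37.7	PASS	DP=45	GT	1/1	0/0
chr2	2450	.	G	A	37.4	PASS	DP=31	GT	0/1	0/0
chr2	2582	.	T	A	62.3	PASS	DP=35	GT	1/1	0/0
chr2	2718	.	G	T	38.0	PASS	DP=30	GT	1/1	0/0
chr2	4950	.	C	T	53.5	PASS	DP=31	GT	1/1	0/0
chr2	6396	.	C	G	34.1	PASS	DP=40	GT	1/1	0/0
chr2	6933	.	T	C	49.2	PASS	DP=38	GT	0/0	1/1
chr2	6977	.	G	T	33.4	PASS	DP=43	GT	0/0	0/1
chr2	7170	.	A	C	65.8	PASS	DP=39	GT	0/1	0/0
chr2	7438	.	T	G	75.9	PASS	DP=37	GT	0/1	1/1
chr2	8236	.	C	G	47.9	PASS	DP=36	GT	0/1	0/1
chr2	8325	.	T	G	56.8	PASS	DP=38	GT	1/1	0/1
chr2	8451	.	A	T	76.5	PASS	DP=41	GT	0/1	0/1
chr2	8659	.	G	C	45.5	PASS	DP=33	GT	0/1	0/0
chr2	8893	.	T	C	47.9	PASS	DP=37	GT	1/1	0/0
chr2	8904	.	A	G	34.0	PASS	DP=35	GT	0/1	1/1
chr2	9114	.	A	G	58.1	PASS	DP=43	GT	0/1	0/0
chr2	9423	.	A	T	42.6	PASS	DP=33	GT	0/1	0/1
chr2	10290	.	G	T	62.4	PASS	DP=35	GT	0/1	0/0
chr2	10371	.	A	G	89.7	PASS	DP=42	GT	0/1	1/1
chr2	10629	.	T	G	79.3	PASS	DP=41	GT	1/1	1/1
chr2	10720	.	C	T	48.0	PASS	DP=55	GT	1/1	0/1
chr2	10997	.	G	A	54.9	PASS	DP=31	GT	1/1	0/0
chr2	12130	.	A	T	58.0	PASS	DP=38	GT	0/1	0/0
chr2	12663	.	C	G	43.9	PASS	DP=39	GT	0/0	0/0
chr2	13192	.	C	G	53.1	PASS	DP=40	GT	0/1	0/0
chr2	13442	.	T	G	76.5	PASS	DP=45	GT	1/1	0/0
chr2	14820	.	G	T	63.3	PASS	DP=46	GT	0/0	0/0
chr2	14865	.	C	T	48.2	PASS	DP=31	GT	0/1	1/1
chr2	15035	.	T	A	49.8	PASS	DP=45	GT	1/1	0/0
chr2	15066	.	T	G	31.5	PASS	DP=47	GT	1/1	0/1
chr2	15394	.	G	T	59.6	PASS	DP=36	GT	0/1	0/1
chr2	16674	.	A	T	82.2	PASS	DP=38	GT	0/0	1/1
chr2	16675	.	A	T	84.5	PASS	DP=43	GT	0/1	1/1
chr2	18040	.	G	C	35.4	PASS	DP=43	GT	0/0	1/1
chr2	18277	.	G	C	65.7	PASS	DP=32	GT	0/0	1/1
chr2	18384	.	A	G	31.8	PASS	DP=42	GT	0/1	0/1
chr2	18564	.	C	G	52.5	PASS	DP=41	GT	0/0	1/1
chr2	18716	.	T	C	72.2	PASS	DP=44	GT	0/1	1/1
chr2	18810	.	G	A	73.0	PASS	DP=36	GT	1/1	1/1
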