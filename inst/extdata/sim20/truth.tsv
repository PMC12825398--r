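gene_id	true_status	true_theta
gene00001	PEG	0.05
gene00002	biparental	0.5
gene00003	biparental	0.5
gene00004	biparental	0.5
gene00005	MEG	0.95
gene00006	biparental	0.5
gene00007	biparental	0.5
gene00008	biparental	0.5
gene00009	biparental	0.5
gene00010	PEG	0.05
gene00011	biparental	0.5
gene00012	biparental	0.5
gene00013	biparental	0.5
gene00014	biparental	0.5
gene00015	biparental	0.5
gene00016	biparental	0.5
gene00017	MEG	0.95
gene00018	biparental	0.5
gene00019	biparental	0.5
gene00020	biparental	0.5
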