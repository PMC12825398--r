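direction_id	mother	father	library_id
P1xP2	P1	P2	P1xP2_rep1
P1xP2	P1	P2	P1xP2_rep2
P1xP2	P1	P2	P1xP2_rep3
P2xP1	P2	P1	P2xP1_rep1
P2xP1	P2	P1	P2xP1_rep2
P2xP1	P2	P1	P2xP1_rep3
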