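gene_id	theta_dir1	theta_dir2	M_pooled	P_pooled	chi2	p_value	q_value	status
gene00001	0.09252669039145907	0.058165548098434	130	1607	1255.9176741508347	4.295923690470613e-275	8.591847380941225e-274	PEG_strong
gene00002	0.4634146341463415	0.5365853658536586	391	388	0.011553273427471117	0.9144033087272484	0.9144033087272484	biparental
gene00003	0.4666666666666667	0.5119047619047619	142	146	0.05555555555555555	0.8136637157667919	0.8564881218597808	biparental
gene00004	0.49340369393139843	0.43490701001430615	678	779	7.001372683596431	0.00814472374504246	0.027149079150141534	biparental
gene00005	0.9923371647509579	0.9453924914675768	536	18	484.3393501805054	2.4295146153988442e-107	1.6196764102658963e-106	MEG_strong
gene00006	0.5934291581108829	0.5990220048899756	534	362	33.017857142857146	9.131629405642205e-9	3.652651762256882e-8	biparental
gene00007	0.4507042253521127	0.44025157232704404	134	167	3.617940199335548	0.05715960153501565	0.1270213367444792	biparental
gene00008	0.48726851851851855	0.5217391304347826	877	861	0.1472957422324511	0.7011331558346435	0.8564881218597808	biparental
gene00009	0.4873501997336884	0.5188556566970091	765	755	0.06578947368421052	0.797568958837549	0.8564881218597808	biparental
gene00010	0.0851063829787234	0.014925373134328358	10	218	189.75438596491227	3.597025015716772e-43	1.7985125078583857e-42	PEG_strong
gene00011	0.5165289256198347	0.5709876543209876	435	373	4.757425742574258	0.02917214702439008	0.07496090133121217	biparental
gene00012	0.49023090586145646	0.5174050632911392	603	592	0.10125523012552301	0.7503284771647671	0.8564881218597808	biparental
gene00013	0.4636363636363636	0.5728155339805825	110	103	0.2300469483568075	0.6314890191801171	0.8564881218597808	biparental
gene00014	0.49466666666666664	0.4654255319148936	721	781	2.396804260985353	0.12158340024068871	0.24316680048137743	biparental
gene00015	0.5062761506276151	0.5290697674418605	818	759	2.2073557387444516	0.13735392666258034	0.24973441211378242	biparental
gene00016	0.5499316005471956	0.5050505050505051	702	623	4.710188679245283	0.029984360532484867	0.07496090133121217	biparental
gene00017	0.9399477806788512	0.9476534296028881	885	52	740.5432230522946	4.567333003603473e-163	4.567333003603473e-162	MEG_strong
gene00018	0.5	0.4838709677419355	462	479	0.3071200850159405	0.5794528165510285	0.8564881218597808	biparental
gene00019	0.4713804713804714	0.5461254612546126	288	280	0.11267605633802817	0.7371178128996823	0.8564881218597808	biparental
gene00020	0.4990791896869245	0.48	571	597	0.5787671232876712	0.4467959753738985	0.7446599589564975	biparental
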