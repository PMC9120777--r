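symbol	locus_tag	organism
bicA1	sll0834	Synechocystis sp. PCC 6803
bicA2	slr0096	Synechocystis sp. PCC 6803
ccaA	slr1347	Synechocystis sp. PCC 6803
ccmK1	sll1029	Synechocystis sp. PCC 6803
ccmK2	sll1028	Synechocystis sp. PCC 6803
ccmK3	slr1838	Synechocystis sp. PCC 6803
ccmK4	slr1839	Synechocystis sp. PCC 6803
ccmL	sll1030	Synechocystis sp. PCC 6803
ccmM	sll1031	Synechocystis sp. PCC 6803
ccmN	sll1032	Synechocystis sp. PCC 6803
ccmO	slr0436	Synechocystis sp. PCC 6803
ccmP	slr0169	Synechocystis sp. PCC 6803
cmpA	slr0040	Synechocystis sp. PCC 6803
cmpB	slr0041	Synechocystis sp. PCC 6803
cmpC	slr0043	Synechocystis sp. PCC 6803
cmpD	slr0044	Synechocystis sp. PCC 6803
cupA	sll1734	Synechocystis sp. PCC 6803
cupB	slr1302	Synechocystis sp. PCC 6803
ecaB	slr0051	Synechocystis sp. PCC 6803
ndhD3	sll1733	Synechocystis sp. PCC 6803
ndhD4	sll0027	Synechocystis sp. PCC 6803
ndhF3	sll1732	Synechocystis sp. PCC 6803
ndhF4	sll0026	Synechocystis sp. PCC 6803
rbcL	slr0009	Synechocystis sp. PCC 6803
rbcS	slr0012	Synechocystis sp. PCC 6803
rbcX	slr0011	Synechocystis sp. PCC 6803
sbtA	slr1512	Synechocystis sp. PCC 6803
sbtB	slr1513	Synechocystis sp. PCC 6803
ecaA	all2929	Anabaena sp. PCC 7120
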