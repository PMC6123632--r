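phylum	specimens	morphotypes	sequences	entities	otus	reads_eotu	eotus	reads_sv	svs
Annelida	163	20	133	23	27	9248	178	9893	63
Gastrotricha	133	37	107	27	38	265	20	1083	12
Mollusca	96	22	81	6	17	4751	36	4423	22
Nematoda	108	37	73	2	37	7818	155	8243	89
Nemertea	94	23	83	9	34	235	12	242	8
Platyhelminthes	208	38	163	42	48	5666	120	5993	87
Xenacoelomorpha	33	10	28	7	10	4223	26	640	12
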