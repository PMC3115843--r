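taxon	p9081	p31283	p48091	p51579	p52165	p67653	p83304	p112753	p122532
O.woodiana	C	T	C	A	T	T	G	A	G
Maui1	C	T	C	A	G	T	G	C	G
Almhiwit5.1	C	G	C	A	T	T	G	C	G
Guangzhou1	C	T	C	A	T	T	T	C	G
GueDeConstantine20	T	T	A	A	T	T	G	C	G
ImouzzerS1	C	T	A	C	T	G	G	C	T
HautAtlas	T	T	A	C	T	G	T	A	G
ManzanillaDeSevilla	T	G	C	C	G	G	T	A	T
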