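haplotype	group	pool	percent
E1.1	Cultivars	cultivated	77.0
E1.2	Cultivars	cultivated	7.0
E1.3	Cultivars	cultivated	1.1
L1.1	Cultivars	cultivated	0.5
E2.1	Cultivars	cultivated	3.2
E2.2	Cultivars	cultivated	1.1
E2.3	Cultivars	cultivated	0.5
E2.4	Cultivars	cultivated	2.1
E2.5	Cultivars	cultivated	0.5
E2.6	Cultivars	cultivated	0.5
E3.1	Cultivars	cultivated	1.1
E3.2	Cultivars	cultivated	5.3
E1.1	BinElOuidane	wild	42.9
E2.1	BinElOuidane	wild	4.8
E2.3	BinElOuidane	wild	4.8
E2.5	BinElOuidane	wild	14.3
E2.6	BinElOuidane	wild	23.8
E2.8	BinElOuidane	wild	14.3
E2.2	Minorca	wild	52.2
E2.3	Minorca	wild	4.3
E3.1	Minorca	wild	26.1
E3.2	Minorca	wild	17.4
E1.1	Pugnochiuso	wild	4.5
E2.1	Pugnochiuso	wild	68.2
E2.2	Pugnochiuso	wild	27.3
E1.1	Gialova	wild	21.6
E1.6	Gialova	wild	8.1
E1.7	Gialova	wild	10.8
E1.8	Gialova	wild	13.5
E1.9	Gialova	wild	13.5
E2.7	Gialova	wild	32.4
E1.1	Rajo	wild	46.2
E1.2	Rajo	wild	26.9
E1.3	Rajo	wild	3.8
E1.4	Rajo	wild	19.2
E1.5	Rajo	wild	3.8
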