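contig	pos	ref	alt
contig_001	2777	C	A
contig_001	2882	T	A
contig_001	3475	A	T
contig_001	3624	G	C
contig_001	4443	T	C
contig_001	8359	G	A
contig_001	12186	C	G
contig_001	12786	G	A
contig_001	13086	C	T
contig_001	13383	A	G
contig_001	16874	G	A
contig_001	18933	A	G
contig_001	20266	C	G
contig_001	20593	A	C
contig_001	21210	A	C
contig_001	22998	A	C
contig_001	24173	T	C
contig_001	24494	A	T
contig_001	27628	C	A
contig_001	28755	A	T
contig_001	29322	T	C
contig_001	30851	T	C
contig_001	32641	G	C
contig_002	691	A	C
contig_002	7732	T	G
contig_002	10357	A	G
contig_002	15503	C	G
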