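position	ref	alt	scheme	raw_score	normalized_score	prediction	source_citation
4450	G	A	tRNA	13	0.650	Possibly/definitely pathogenic	curated
4271	A	G	tRNA	3	0.150	Neutral	synthetic-example
12148	T	C	tRNA	11	0.550	Possibly/definitely pathogenic	synthetic-example
850	A	G	rRNA	1	0.200	Undetermined	synthetic-example
2300	T	C	rRNA	4	0.800	Expectedly pathogenic	synthetic-example
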