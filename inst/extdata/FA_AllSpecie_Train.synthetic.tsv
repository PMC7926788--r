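pdb_id	chain	ligand_code	species	label
11H9	A	DAO	Schizosaccharomyces pombe	1
5VV2	A	HXA	Aspergillus niger	1
3Y0K	A	STE	Escherichia coli	1
5GME	A	LNL	Pseudomonas aeruginosa	1
8YTM	A	PAE	Yersinia pestis	1
8U5V	A	LNL	Oryza sativa	1
7VG3	A	ARA	Caenorhabditis elegans	1
1V8W	A	LAU	Bombyx mori	1
9XNN	A	LNL	Macaca mulatta	1
4BFB	A	DAO	Canis lupus	1
6QPD	A	OCA	Capra hircus	1
9WDM	A	EPA	Felis catus	1
2H6E	A	HXA	Mycobacterium tuberculosis	1
7P72	A	LNL	Pan troglodytes	1
553E	A	ARA	Solanum lycopersicum	1
4VS8	A	PLM	Homo sapiens	1
36CQ	A	MLR	Oncorhynchus mykiss	1
1S0D	A	ARA	Gallus gallus	1
6RGY	A	DKA	Ovis aries	1
2VTK	A	EPA	Toxoplasma gondii	1
1AT6	A	ARA	Leishmania major	1
8P0U	A	LAU	Oryctolagus cuniculus	1
3WY2	A	EPA	Bacillus subtilis	1
2RQ0	A	HXA	Gadus morhua	1
4S5K	A	OLA	Drosophila melanogaster	1
7MES	A	MYR	Squalus acanthias	1
3U1Z	A	HXA	Thermus thermophilus	1
3CIX	A	PAE	Zea mays	1
6831	A	DKA	Saccharomyces cerevisiae	1
9R3N	A	HXA	Anopheles gambiae	1
953M	A	MYR	Salmo salar	1
851S	A	STE	Staphylococcus aureus	1
8ND2	A	PAE	Vibrio cholerae	1
55GS	A	HXA	Anas platyrhynchos	1
4KMC	A	PLM	Homo sapiens	1
49RW	A	PAE	Drosophila melanogaster	1
5MU6	A	PLM	Escherichia coli	1
7W6X	A	HXA	Zea mays	1
2LSX	A	EPA	Pseudomonas aeruginosa	1
1LF3	A	PAE	Takifugu rubripes	1
6ACA	A	DAO	Yersinia pestis	1
85EK	A	LAU	Candida albicans	1
9171	A	DAO	Apis mellifera	1
3FN5	A	ARA	Vibrio cholerae	1
6TAJ	A	HXA	Neurospora crassa	1
8E77	A	LAU	Mus musculus	1
54CH	A	PAE	Ovis aries	1
6A9E	A	STE	Staphylococcus aureus	1
1LWP	A	MYR	Danio rerio	1
7X1O	A	PLM	Trypanosoma brucei	1
9C8C	A	DKA	Sus scrofa	1
8SR3	A	HXA	Leishmania major	1
1ANE	A	OLA	Plasmodium falciparum	1
3YGY	A	DKA	Glycine max	1
1A8L	A	DKA	Listeria monocytogenes	1
8PCP	A	ARA	Aspergillus niger	1
9QMW	A	EPA	Felis catus	1
9ZQD	A	EPA	Bos taurus	1
9ZIJ	A	PLM	Plasmodium falciparum	1
558F	A	PAE	Anopheles gambiae	1
90JS	A	MYR	Danio rerio	1
7SZ9	A	STE	Equus caballus	1
52S2	A	DKA	Streptococcus pneumoniae	1
4SCI	A	MLR	Oncorhynchus mykiss	1
3Z6Z	A	MLR	Xenopus laevis	1
54V3	A	LNL	Rattus norvegicus	1
7MIS	A	MLR	Helicobacter pylori	1
5OPB	A	ARA	Bombyx mori	1
9574	A	MYR	Arabidopsis thaliana	1
37YG	A	DKA	Equus caballus	1
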