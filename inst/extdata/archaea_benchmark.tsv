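organism	refseq	reference_oriCs	predicted_oriCs	true_positives
Aeropyrum pernix K1	NC_000854	2	2	1
Pyrococcus abyssi GE5	NC_000868	1	1	1
Methanothermobacter thermautotrophicus str. Delta H	NC_000916	1	2	1
Archaeoglobus fulgidus DSM 4304	NC_000917	1	1	0
Pyrococcus horikoshii OT3	NC_000961	1	1	1
Halobacterium sp. NRC-1	NC_002607	2	4	2
Pyrococcus furiosus DSM 3638	NC_003413	1	1	1
Hyperthermus butylicus DSM 5456	NC_008818	2	1	1
Pyrobaculum calidifontis JCM 11548	NC_009073	1	1	0
Haloferax volcanii DS2	NC_013967	5	6	5
Haloarcula hispanica ATCC 33960 chromosome II	NC_015943	4	7	3
Haloarcula hispanica ATCC 33960 chromosome I	NC_015948	5	1	1
Nitrosopumilus maritimus SCM1	NC_010085	1	1	1
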