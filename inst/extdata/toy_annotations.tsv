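chrom	pos	nonunique_map_frac	multimap_cluster	excessive_depth	dust_score
1	100	0.95	FALSE	FALSE	10
1	200	0.95	FALSE	FALSE	10
1	300	0.95	FALSE	FALSE	10
1	400	0.95	FALSE	FALSE	10
1	500	0.95	FALSE	FALSE	10
1	600	0.95	FALSE	FALSE	65
1	700	0.50	FALSE	FALSE	65
1	800	0.95	TRUE	TRUE	10
1	900	0.95	FALSE	FALSE	10
1	1000	0.95	FALSE	FALSE	10
2	100	0.50	TRUE	TRUE	65
2	200	0.95	FALSE	FALSE	10
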