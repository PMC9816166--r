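##fileformat=VCFv4.2
##INFO=<ID=TNC,Number=1,Type=String,Description="Pyrimidine-centered trinucleotide context">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR	NORMAL
1	100	.	C	T	.	PASS	TNC=ACA	GT:AD:DP	0/1:30,20:50	0/0:40,0:40
1	200	.	C	T	.	PASS	TNC=ACG	GT:AD:DP	0/1:5,4:9	0/0:40,0:40
1	300	.	C	A	.	PASS	TNC=GCA	GT:AD:DP	0/1:30,10:40	0/0:9,0:9
1	400	.	T	C	.	PASS	TNC=ATA	GT:AD:DP	0/1:25,10:35	0/0:38,2:40
1	500	.	T	G	.	PASS	TNC=CTC	GT:AD:DP	0/1:25,12:37	0/0:39,1:40
1	600	.	C	T	.	PASS	TNC=TCT	GT:AD:DP	0/1:28,12:40	0/0:41,0:41
1	700	.	C	G	.	PASS	TNC=ACC	GT:AD:DP	0/1:27,13:40	0/0:42,0:42
1	800	.	T	A	.	PASS	TNC=GTG	GT:AD:DP	0/1:26,14:40	0/0:43,0:43
1	900	.	C	T	.	PASS	TNC=ACG	GT:AD:DP	0/1:24,16:40	0/0:44,0:44
1	1000	.	C	T	.	PASS	TNC=TCG	GT:AD:DP	0/1:23,17:40	0/0:45,0:45
2	100	.	C	T	.	PASS	TNC=CCA	GT:AD:DP	0/1:22,18:40	0/0:46,0:46
2	200	.	T	C	.	PASS	TNC=TTT	GT:AD:DP	0/1:21,19:40	0/0:47,0:47
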