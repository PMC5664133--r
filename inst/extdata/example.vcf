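##fileformat=VCFv4.2
##source=synthetic example cohort (hand-written, illustrative coordinates)
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S01	S02	S03	S04
chr4	15989860	rs3130	A	G	812	PASS	GENE=PROM1	GT:AD:DP	0/1:20,44:64	0/1:18,40:58	0/1:35,33:68	0/0:70,0:70
chr10	85968105	rs4933980	T	C	640	PASS	GENE=CDHR1	GT:AD:DP	0/1:52,18:70	0/1:61,20:81	1/1:0,75:75	0/1:44,15:59
chr11	6172237	rs149698	C	T	500	PASS	GENE=BEST1	GT:AD:DP	0/1:12,40:52	0/1:30,29:59	./.:.:.	0/1:25,27:52
chr11	61731289	.	G	A	700	PASS	GENE=BEST1	GT:AD:DP	0/1:33,30:63	0/1:29,31:60	0/1:30,34:64	0/1:41,38:79
chr2	170336099	rs7589199	C	A	150	PASS	GENE=BBS5	GT:AD:DP	0/1:25,26:51	0/1:22,30:52	0/1:28,24:52	0/1:30,31:61
chr5	146258291	rs2071246	G	T	901	PASS	GENE=GRM6	GT:AD:DP	0/1:40,41:81	0/1:36,38:74	0/1:52,20:72	0/1:39,40:79
chr1	94473807	rs1762114	C	G,T	633	PASS	GENE=ABCA4	GT:AD:DP	1/2:0,30,31:61	0/1:28,30,0:58	0/1:25,24,0:49	0/0:60,0,0:60
chr8	55538695	rs29001637	CT	C	560	PASS	GENE=RP1	GT:AD:DP	0/1:30,28:58	0/1:25,27:52	0/0:61,0:61	0/1:33,30:63
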