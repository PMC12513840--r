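##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=AB,Number=1,Type=Float,Description="Heterozygous allele balance">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMP01	SAMP02	SAMP03	SAMP04	SAMP05	SAMP06	SAMP07	SAMP08	SAMP09	SAMP10	SAMP11	SAMP12	SAMP13	SAMP14	SAMP15	SAMP16	SAMP17	SAMP18	SAMP19	SAMP20
1	1000	v01	A	G	.	PASS	.	GT:DP:GQ:AB	1/1:5:60:0.500	1/1:5:60:0.500	0/0:5:60:0.500	0/1:5:60:0.500	0/1:5:60:0.500	0/1:5:60:0.500	0/1:5:60:0.500	0/0:5:60:0.500	0/1:5:60:0.500	0/1:5:60:0.500	0/0:5:60:0.500	0/1:5:60:0.500	1/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	1/1:30:60:0.500	1/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500
1	2000	v02	A	G	.	PASS	.	GT:DP:GQ:AB	1/1:5:60:0.500	0/0:5:60:0.500	1/1:5:60:0.500	1/1:5:60:0.500	0/0:5:60:0.500	0/1:5:60:0.500	0/0:5:60:0.500	1/1:5:60:0.500	0/0:5:60:0.500	0/1:5:60:0.500	0/1:5:60:0.500	0/1:5:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	1/1:30:60:0.500	0/1:30:60:0.500
1	3000	v03	A	G	.	PASS	.	GT:DP:GQ:AB	0/0:5:60:0.500	0/0:5:60:0.500	0/0:5:60:0.500	1/1:5:60:0.500	0/0:5:60:0.500	1/1:5:60:0.500	1/1:5:60:0.500	0/1:5:60:0.500	1/1:5:60:0.500	0/1:5:60:0.500	0/0:5:60:0.500	0/0:5:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500
1	4000	v04	A	G	.	PASS	.	GT:DP:GQ:AB	0/1:30:60:0.900	1/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500
1	5000	v05	A	G	.	PASS	.	GT:DP:GQ:AB	0/1:30:60:0.900	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	1/1:30:60:0.500	1/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500
1	6000	v06	A	G	.	PASS	.	GT:DP:GQ:AB	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	./.:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500
1	7000	v07	A	G	.	PASS	.	GT:DP:GQ:AB	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	1/1:30:60:0.500	1/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	1/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	1/1:30:60:0.500	1/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500
1	8000	v08	A	G	.	PASS	.	GT:DP:GQ:AB	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	1/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500
1	9000	v09	A	G	.	PASS	.	GT:DP:GQ:AB	1/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500
1	10000	v10	A	G	.	PASS	.	GT:DP:GQ:AB	1/1:30:60:0.500	1/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500	1/1:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/0:30:60:0.500	0/1:30:60:0.500	0/1:30:60:0.500
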