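##fileformat=VCFv4.2
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	rep1	rep2	rep3	panel1	panel2	panel3	panel4
sim_1	20000	.	A	C	.	PASS	.	AD	2,1	0,6	1,1	0,6	8,0	4,0	0,9
sim_1	40000	.	A	C	.	PASS	.	AD	1,2	2,2	3,1	2,0	0,8	2,1	2,0
sim_1	60000	.	A	C	.	PASS	.	AD	1,1	2,1	0,7	1,6	0,6	6,0	0,11
sim_1	80000	.	A	C	.	PASS	.	AD	0,4	2,5	0,3	5,0	3,1	0,6	0,6
sim_1	100000	.	A	C	.	PASS	.	AD	2,0	1,1	4,0	4,2	3,4	6,0	9,0
sim_1	120000	.	A	C	.	PASS	.	AD	2,0	3,0	3,0	3,4	3,1	2,1	4,0
sim_1	140000	.	A	C	.	PASS	.	AD	1,3	2,1	3,2	1,0	4,0	3,2	3,0
sim_1	160000	.	A	C	.	PASS	.	AD	3,0	0,1	1,0	0,4	2,2	4,1	3,2
sim_1	180000	.	A	C	.	PASS	.	AD	0,4	0,2	1,3	4,5	5,0	5,2	6,0
sim_1	200000	.	A	C	.	PASS	.	AD	4,1	0,5	2,2	7,0	0,6	0,5	1,4
sim_1	220000	.	A	C	.	PASS	.	AD	0,8	0,2	0,1	4,1	4,0	2,4	7,0
sim_1	240000	.	A	C	.	PASS	.	AD	0,4	4,0	1,5	3,2	5,0	0,4	4,0
sim_1	260000	.	A	C	.	PASS	.	AD	0,1	3,3	0,0	4,0	9,0	3,3	7,0
sim_1	280000	.	A	C	.	PASS	.	AD	3,1	1,1	1,1	3,3	5,0	1,5	4,4
sim_1	300000	.	A	C	.	PASS	.	AD	3,3	3,5	2,1	0,4	4,3	4,0	7,3
sim_1	320000	.	A	C	.	PASS	.	AD	0,2	1,2	1,1	3,1	0,8	2,3	4,0
sim_1	340000	.	A	C	.	PASS	.	AD	0,3	0,0	1,3	0,8	3,4	0,5	0,6
sim_1	360000	.	A	C	.	PASS	.	AD	0,6	2,2	0,6	0,8	0,5	0,7	5,0
sim_1	380000	.	A	C	.	PASS	.	AD	4,0	3,1	5,0	3,2	0,7	3,4	5,3
sim_1	400000	.	A	C	.	PASS	.	AD	3,5	5,0	0,2	5,2	9,0	4,3	6,2
sim_1	420000	.	A	C	.	PASS	.	AD	3,2	1,2	2,4	5,0	5,2	1,1	0,4
sim_1	440000	.	A	C	.	PASS	.	AD	6,0	4,0	7,0	7,0	3,0	2,4	0,8
sim_1	460000	.	A	C	.	PASS	.	AD	3,0	2,0	2,3	1,6	8,0	9,0	0,5
sim_1	480000	.	A	C	.	PASS	.	AD	4,0	1,4	6,0	0,6	6,1	0,3	7,0
sim_1	500000	.	A	C	.	PASS	.	AD	0,2	2,0	0,4	1,2	3,2	4,2	3,0
sim_1	520000	.	A	C	.	PASS	.	AD	5,0	3,0	1,0	9,0	0,3	5,0	5,4
sim_1	540000	.	A	C	.	PASS	.	AD	0,2	4,1	0,6	1,6	3,4	7,0	2,0
sim_1	560000	.	A	C	.	PASS	.	AD	2,1	1,3	0,2	0,9	2,7	6,1	0,7
sim_1	580000	.	A	C	.	PASS	.	AD	0,7	0,4	0,3	0,3	0,9	12,0	0,4
sim_1	600000	.	A	C	.	PASS	.	AD	0,3	0,3	0,8	3,1	4,3	0,4	3,0
sim_1	620000	.	A	C	.	PASS	.	AD	7,4	2,4	1,1	1,1	4,4	5,6	4,1
sim_1	640000	.	A	C	.	PASS	.	AD	0,2	3,4	0,4	1,4	4,2	6,4	1,0
sim_1	660000	.	A	C	.	PASS	.	AD	2,2	2,1	2,1	0,8	0,10	1,2	0,7
sim_1	680000	.	A	C	.	PASS	.	AD	4,0	2,1	5,0	3,1	4,3	0,5	4,5
sim_1	700000	.	A	C	.	PASS	.	AD	5,1	4,3	3,0	0,5	2,5	7,0	4,7
sim_1	720000	.	A	C	.	PASS	.	AD	1,2	1,0	3,0	0,5	0,7	4,3	0,5
sim_1	740000	.	A	C	.	PASS	.	AD	2,0	0,4	5,0	3,4	10,0	2,1	6,0
sim_1	760000	.	A	C	.	PASS	.	AD	1,3	2,3	3,2	0,6	3,3	1,1	11,0
sim_1	780000	.	A	C	.	PASS	.	AD	4,2	0,5	1,1	6,0	7,0	0,4	8,7
sim_1	800000	.	A	C	.	PASS	.	AD	1,1	2,0	1,2	0,3	1,3	1,4	1,2
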