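chrom	pos	freq_B
sim_1	20000	0.6913
sim_1	40000	0.4198
sim_1	60000	0.4677
sim_1	80000	0.4715
sim_1	100000	0.5474
sim_1	120000	0.3908
sim_1	140000	0.5415
sim_1	160000	0.3612
sim_1	180000	0.3857
sim_1	200000	0.4573
sim_1	220000	0.5368
sim_1	240000	0.4243
sim_1	260000	0.4699
sim_1	280000	0.5019
sim_1	300000	0.5078
sim_1	320000	0.5029
sim_1	340000	0.6976
sim_1	360000	0.5988
sim_1	380000	0.488
sim_1	400000	0.354
sim_1	420000	0.6102
sim_1	440000	0.4299
sim_1	460000	0.5918
sim_1	480000	0.6462
sim_1	500000	0.487
sim_1	520000	0.3867
sim_1	540000	0.4954
sim_1	560000	0.494
sim_1	580000	0.6988
sim_1	600000	0.6586
sim_1	620000	0.6651
sim_1	640000	0.5335
sim_1	660000	0.679
sim_1	680000	0.5536
sim_1	700000	0.5566
sim_1	720000	0.6601
sim_1	740000	0.5111
sim_1	760000	0.4436
sim_1	780000	0.4197
sim_1	800000	0.6519
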