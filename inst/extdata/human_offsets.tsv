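# Mapping from motif offsets to canonical human P2X7 residue numbers.
# Anchored on printed landmarks: I507TTS pins cluster2 (start = 497, so the
# preceding residue is E496); F/Y581-P582 and the terminal G590 pin cluster3
# (start = 569, preceding residue I568); R546-H547, Y550 and W559 pin the
# inter-cluster R(H/Y)x2Yx8WRF block. Offset 0 means the residue immediately
# before the motif. Cluster1 has no printed human anchor and is omitted.
motif	offset	human_pos
cluster2	0	496
cluster2	1	497
cluster2	2	498
cluster2	3	499
cluster2	4	500
cluster2	5	501
cluster2	6	502
cluster2	7	503
cluster2	8	504
cluster2	9	505
cluster2	10	506
cluster2	11	507
cluster2	12	508
cluster2	13	509
cluster2	14	510
cluster3	0	568
cluster3	1	569
cluster3	2	570
cluster3	3	571
cluster3	4	572
cluster3	5	573
cluster3	6	574
cluster3	7	575
cluster3	8	576
cluster3	9	577
cluster3	10	578
cluster3	11	579
cluster3	12	580
cluster3	13	581
cluster3	14	582
cluster3	15	583
cluster3	16	584
cluster3	17	585
cluster3	18	586
cluster3	19	587
cluster3	20	588
cluster3	21	589
cluster3	22	590
gdp_rh_block	1	546
gdp_rh_block	2	547
gdp_rh_block	5	550
gdp_rh_block	14	559
gdp_rh_block	15	560
gdp_rh_block	16	561
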