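# mirvar nearest-neighbor energy parameters, version 1 (kcal/mol, 37 C)
category	key	size	value
stack	AU:AU	NA	-0.93
stack	AU:UA	NA	-1.1
stack	AU:CG	NA	-2.24
stack	AU:GC	NA	-2.08
stack	AU:GU	NA	-0.55
stack	AU:UG	NA	-1.36
stack	UA:AU	NA	-1.33
stack	UA:UA	NA	-0.93
stack	UA:CG	NA	-2.35
stack	UA:GC	NA	-2.11
stack	UA:GU	NA	-1.27
stack	UA:UG	NA	-1
stack	CG:AU	NA	-2.11
stack	CG:UA	NA	-2.08
stack	CG:CG	NA	-3.26
stack	CG:GC	NA	-2.36
stack	CG:GU	NA	-1.41
stack	CG:UG	NA	-2.11
stack	GC:AU	NA	-2.35
stack	GC:UA	NA	-2.24
stack	GC:CG	NA	-3.42
stack	GC:GC	NA	-3.26
stack	GC:GU	NA	-1.53
stack	GC:UG	NA	-2.51
stack	GU:AU	NA	-1
stack	GU:UA	NA	-1.36
stack	GU:CG	NA	-2.51
stack	GU:GC	NA	-2.11
stack	GU:GU	NA	-0.5
stack	GU:UG	NA	0.47
stack	UG:AU	NA	-1.27
stack	UG:UA	NA	-0.55
stack	UG:CG	NA	-1.53
stack	UG:GC	NA	-1.41
stack	UG:GU	NA	-0.3
stack	UG:UG	NA	-0.5
hairpin	NA	1	NA
hairpin	NA	2	NA
hairpin	NA	3	5.4
hairpin	NA	4	5.6
hairpin	NA	5	5.7
hairpin	NA	6	5.4
hairpin	NA	7	6
hairpin	NA	8	5.5
hairpin	NA	9	6.4
hairpin	NA	10	6.5137
hairpin	NA	11	6.6165
hairpin	NA	12	6.7104
hairpin	NA	13	6.7968
hairpin	NA	14	6.8767
hairpin	NA	15	6.9512
hairpin	NA	16	7.0208
hairpin	NA	17	7.0862
hairpin	NA	18	7.1479
hairpin	NA	19	7.2062
hairpin	NA	20	7.2616
hairpin	NA	21	7.3142
hairpin	NA	22	7.3644
hairpin	NA	23	7.4124
hairpin	NA	24	7.4583
hairpin	NA	25	7.5024
hairpin	NA	26	7.5447
hairpin	NA	27	7.5854
hairpin	NA	28	7.6246
hairpin	NA	29	7.6625
hairpin	NA	30	7.6991
bulge	NA	1	3.8
bulge	NA	2	2.8
bulge	NA	3	3.2
bulge	NA	4	3.6
bulge	NA	5	4
bulge	NA	6	4.4
bulge	NA	7	4.5663
bulge	NA	8	4.7104
bulge	NA	9	4.8375
bulge	NA	10	4.9512
bulge	NA	11	5.054
bulge	NA	12	5.1479
bulge	NA	13	5.2343
bulge	NA	14	5.3142
bulge	NA	15	5.3887
bulge	NA	16	5.4583
bulge	NA	17	5.5237
bulge	NA	18	5.5854
bulge	NA	19	5.6437
bulge	NA	20	5.6991
bulge	NA	21	5.7517
bulge	NA	22	5.8019
bulge	NA	23	5.8499
bulge	NA	24	5.8958
bulge	NA	25	5.9399
bulge	NA	26	5.9822
bulge	NA	27	6.0229
bulge	NA	28	6.0621
bulge	NA	29	6.1
bulge	NA	30	6.1366
internal	NA	1	NA
internal	NA	2	1.5
internal	NA	3	1.6
internal	NA	4	1.7
internal	NA	5	2
internal	NA	6	2.2
internal	NA	7	2.3663
internal	NA	8	2.5104
internal	NA	9	2.6375
internal	NA	10	2.7512
internal	NA	11	2.854
internal	NA	12	2.9479
internal	NA	13	3.0343
internal	NA	14	3.1142
internal	NA	15	3.1887
internal	NA	16	3.2583
internal	NA	17	3.3237
internal	NA	18	3.3854
internal	NA	19	3.4437
internal	NA	20	3.4991
internal	NA	21	3.5517
internal	NA	22	3.6019
internal	NA	23	3.6499
internal	NA	24	3.6958
internal	NA	25	3.7399
internal	NA	26	3.7822
internal	NA	27	3.8229
internal	NA	28	3.8621
internal	NA	29	3.9
internal	NA	30	3.9366
const	terminal_au	NA	0.45
const	duplex_init	NA	4.09
const	ml_init	NA	3.4
const	ml_branch	NA	0.4
const	ml_unpaired	NA	0
const	temperature	NA	310.15
const	RT	NA	0.6163
const	min_hairpin	NA	3
const	max_loop_side	NA	15
const	loop_extrap	NA	1.079
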