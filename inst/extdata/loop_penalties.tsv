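loop_type	size	dg
hairpin	3	5.4
hairpin	4	5.6
hairpin	5	5.7
hairpin	6	5.4
hairpin	7	6
hairpin	8	5.5
hairpin	9	6.4
hairpin	10	6.51
hairpin	11	6.62
hairpin	12	6.71
hairpin	13	6.8
hairpin	14	6.88
hairpin	15	6.95
hairpin	16	7.02
hairpin	17	7.09
hairpin	18	7.15
hairpin	19	7.21
hairpin	20	7.26
hairpin	21	7.32
hairpin	22	7.37
hairpin	23	7.41
hairpin	24	7.46
hairpin	25	7.5
hairpin	26	7.55
hairpin	27	7.59
hairpin	28	7.63
hairpin	29	7.66
hairpin	30	7.7
bulge	1	3.8
bulge	2	2.8
bulge	3	3.2
bulge	4	3.6
bulge	5	4
bulge	6	4.4
bulge	7	4.57
bulge	8	4.71
bulge	9	4.84
bulge	10	4.95
bulge	11	5.05
bulge	12	5.15
bulge	13	5.24
bulge	14	5.32
bulge	15	5.39
bulge	16	5.46
bulge	17	5.52
bulge	18	5.59
bulge	19	5.64
bulge	20	5.7
bulge	21	5.75
bulge	22	5.8
bulge	23	5.85
bulge	24	5.9
bulge	25	5.94
bulge	26	5.98
bulge	27	6.02
bulge	28	6.06
bulge	29	6.1
bulge	30	6.14
internal	2	1.5
internal	3	1.8
internal	4	2
internal	5	2.2
internal	6	2.5
internal	7	2.67
internal	8	2.81
internal	9	2.94
internal	10	3.05
internal	11	3.15
internal	12	3.25
internal	13	3.34
internal	14	3.42
internal	15	3.49
internal	16	3.56
internal	17	3.62
internal	18	3.69
internal	19	3.74
internal	20	3.8
internal	21	3.85
internal	22	3.9
internal	23	3.95
internal	24	4
internal	25	4.04
internal	26	4.08
internal	27	4.12
internal	28	4.16
internal	29	4.2
internal	30	4.24
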