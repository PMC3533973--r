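grand_parent	family	family_size	n_selfed	n_outcrossed	n_contaminant
NL94 LYE 16x13	NS33	6	0	6	0
NL94 LYE 16x13	NS81	8	0	7	1
NL94 LYE 16x13	NS85	7	6	1	0
NL94 LYE 16x13	NS225	7	0	0	7
NL94 LYE 16x13	NS313	10	0	10	0
NL94 LYE 16x13	NS387	8	0	7	1
SL93 7x15	SN4	1	0	0	1
SL93 7x15	SN6	11	0	1	10
SL93 7x15	SN9	2	0	0	2
SL93 7x15	SN11	7	0	1	6
SL93 7x15	SN16	2	2	0	0
SL93 7x15	SN17	1	1	0	0
SL93 7x15	SN18	1	0	1	0
SL93 7x15	SN19	1	0	0	1
SL93 7x15	SN25	4	0	4	0
SL93 7x15	SN30	1	0	1	0
SL93 7x15	SN31	1	0	1	0
SL93 7x15	SN33	5	0	3	2
SL93 7x15	SN34	13	0	11	2
SL93 7x15	SN38	1	0	0	1
SL93 7x15	SN41	1	0	1	0
SL93 7x15	SN44	1	1	0	0
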