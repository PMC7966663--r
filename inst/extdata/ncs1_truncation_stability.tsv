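variant	terminal_residue	charge	dG_N	dG_N_sd	dG_C	dG_C_sd
WT	Val190	-9	42.0	1.9	42.0	2.8
D190	Leu189	-9	47.0	4.1	43.4	2.8
D189	Gly188	-9	43.1	3.1	45.4	3.1
D188	Asp187	-9	45.4	2.4	43.9	1.7
D187	Tyr186	-8	43.9	2.2	43.2	1.9
D186	Leu185	-8	43.5	1.8	46.0	1.4
D185	Ser184	-8	37.2	3.3	43.2	1.6
D184	Leu183	-8	34.8	3.4	43.8	2.7
D182	Gln181	-8	27.2	2.8	39.7	3.0
D180	Ile179	-8	31.1	5.1	38.3	2.8
D178	Pro177	-8	22.8	1.7	40.8	4.4
D176	Ala175	-7	29.9	2.4	41.0	2.3
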