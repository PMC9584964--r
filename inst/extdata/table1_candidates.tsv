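enzyme	label	transcript_ids	ec	pfam	size_bp	size_aa	size_kda	incomplete
PKR	PKR1	TRINITY_DN97220_c2_g4_i5	1.1.1.100;2.3.1.85	PF00106;PF13561;PF08659	1194	398	42.29	FALSE
PKR	PKR2	TRINITY_DN99958_c0_g2_i3	1.1.1.100;2.3.1.85	PF00106;PF13561;PF08659	963	321	33.39	FALSE
AAT	AAT1	TRINITY_DN100028_c0_g1_i9	2.6.1.4;2.6.1.2;2.6.1.44;2.6.1.12	PF00155	1443	481	53.27	FALSE
AAT	AAT2	TRINITY_DN101579_c0_g1_i4	2.6.1.2;2.6.1.12	PF00155	1638	546	60.01	FALSE
AAT	AAT3	TRINITY_DN92259_c1_g1_i5/TRINITY_DN92259_c1_g2_i1		PF00202	1422	474	51.76	FALSE
AAT	AAT4	TRINITY_DN98702_c1_g1_i2	2.6.1.96;2.6.1.62	PF00202	1413	471	52.13	FALSE
AAT	AAT5	TRINITY_DN99413_c0_g2_i6	2.6.1.4;2.6.1.2;2.6.1.44;2.6.1.12	PF00155	1437	479	52.81	FALSE
AAT	AAT6	TRINITY_DN99413_c0_g2_i8	2.6.1.4;2.6.1.2;2.6.1.44;2.6.1.12	PF00155	1437	479	52.95	FALSE
CR	CR1	TRINITY_DN86784_c0_g1_i2/TRINITY_DN86784_c0_g2_i1		PF13561;PF00106	912	304	32.06	FALSE
CR	CR2	TRINITY_DN92324_c0_g1_i1		PF13561;PF00106	891	297	31.44	FALSE
CR	CR3	TRINITY_DN92324_c0_g1_i3		PF13561;PF00106	741	247	26.03	FALSE
CR	CR4	TRINITY_DN93222_c2_g6_i1	1.3.1.33;1.1.1.2	PF00106	732	244	27.19	FALSE
CR	CR5	TRINITY_DN93586_c1_g1_i1	1.1.1.330;1.3.1.33	PF00106	945	315	34.29	FALSE
CR	CR6	TRINITY_DN93845_c0_g1_i3	1.3.1.33;1.1.1.330	PF00106	636	212	22.86	FALSE
CR	CR7	TRINITY_DN95493_c4_g1_i3	1.1.1.330;1.3.1.33	PF00106	771	257	28.25	FALSE
CSAM	CSAM1	TRINITY_DN100232_c1_g3_i3		PF03492	399	133	15.21	FALSE
CSAM	CSAM2	TRINITY_DN109295_c0_g1_i1			492	164	18.78	FALSE
CSAM	CSAM3	TRINITY_DN83407_c0_g2_i2		PF03492	474	158	17.82	FALSE
CSAM	CSAM4	TRINITY_DN91104_c0_g1_i3		PF03492	1107	369	41.43	FALSE
CSAM	CSAM5	TRINITY_DN91104_c0_g1_i9		PF03492	669	223	25.37	TRUE
CSAM	CSAM6	TRINITY_DN95275_c3_g1_i1/TRINITY_DN99752_c3_g3_i3		PF03492	1071	357	40.43	FALSE
CSAM	CSAM7	TRINITY_DN95333_c0_g1_i17		PF03492	438	146	16.39	FALSE
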