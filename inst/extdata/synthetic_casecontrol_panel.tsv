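id	status	disease0	M01	M02	M03	M04	M05	M06	M07	M08	M09	M10	M11	M12
S01	case	1	1	1	1	0	2	2	2	2	2	2	2	0
S02	case	1	1	2	1	1	1	2	1	0	2	1	0	1
S03	case	1	1	2	2	1	1	2	1	0	0	2	1	0
S04	case	1	1	1	1	2	1	2	2	0	1	2	1	0
S05	case	1	1	1	1	2	2	1	2	0	1	2	2	0
S06	case	1	2	1	1	2	2	2	2	1	1	2	1	0
S07	case	1	1	1	1	2	2	1	2	1	0	1	2	0
S08	case	1	2	2	.	1	1	2	1	1	2	1	2	0
S09	case	1	1	1	1	1	0	2	1	0	1	2	2	0
S10	case	1	2	1	2	1	0	2	1	0	2	1	1	0
S11	case	1	2	1	1	2	1	2	1	0	2	2	1	1
S12	case	1	1	2	0	0	2	2	1	0	0	2	1	0
S13	case	1	2	0	1	1	2	2	2	0	1	2	1	0
S14	case	1	2	1	2	2	1	2	2	1	1	2	1	0
S15	case	1	2	1	0	1	1	2	1	0	1	1	1	1
S16	case	1	1	1	0	2	1	1	0	0	1	2	0	0
S17	control	0	1	1	.	1	2	2	2	1	2	1	0	1
S18	control	0	1	0	0	2	2	1	.	1	2	2	1	1
S19	control	0	1	2	0	1	1	1	1	1	1	1	0	0
S20	control	0	1	1	0	1	1	2	2	0	1	2	1	0
S21	control	0	2	1	0	0	.	2	2	1	1	2	1	1
S22	control	0	2	1	0	2	2	1	1	0	2	2	0	0
S23	control	0	2	2	0	2	1	2	1	0	2	0	2	0
S24	control	0	2	1	0	0	2	1	1	1	2	2	2	0
S25	control	0	1	1	1	2	0	1	2	0	1	1	2	1
S26	control	0	1	1	.	1	2	2	1	0	2	2	2	1
S27	control	0	0	2	1	1	0	2	2	0	2	2	0	1
S28	control	0	1	0	0	2	2	2	2	1	1	2	1	0
S29	control	0	1	1	0	1	0	0	1	0	1	2	2	0
S30	control	0	2	1	1	1	2	2	1	0	2	2	2	0
S31	control	0	2	0	0	1	1	2	2	0	1	1	1	1
S32	control	0	2	1	0	2	1	2	2	1	2	2	1	0
S33	control	0	0	0	0	2	1	2	0	2	2	2	0	0
S34	control	0	2	0	0	1	1	2	2	0	2	2	2	0
S35	control	0	0	1	0	1	2	1	1	0	1	2	1	0
S36	control	0	0	1	0	1	1	2	2	1	2	1	1	1
S37	control	0	1	1	2	2	1	2	2	0	1	1	1	0
S38	control	0	2	0	0	2	1	.	2	2	2	2	2	0
S39	control	0	2	0	0	1	0	2	1	1	1	2	1	0
S40	control	0	2	2	0	1	0	2	1	1	0	2	0	0
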