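feature	case_pos	case_n	control_pos	control_n
gender_female	87	92	28	34
dry_mouth	45	90	14	33
dry_eye	30	91	11	33
anti_SSA	63	91	4	33
anti_SSB	30	90	3	34
anti_ANA	50	90	19	33
anti_Ro	56	89	4	33
gland_atrophy	78	86	6	24
lymphocytic_infiltration	45	86	1	34
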