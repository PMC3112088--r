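breakpoint_id	segment	class	branch	cluster_context	centromere_context	sub_position	centromere_fate
bp01	17p	translocation	stem_M_plathytrix	present	1	between_centromere_and_cluster	lost_then_reacquired
bp02	17p	fission	within_Coelomys	present	1	between_centromere_and_cluster	lost_then_reacquired
bp03	8p	fusion	stem_M_musculoides	present	1	between_centromere_and_cluster	lost_then_reacquired
bp04	19	fission	stem_subgenus_Mus	present	1	between_centromere_and_cluster	lost_then_reacquired
bp05	6	inversion	stem_Nannomys	present	1	between_centromere_and_cluster	lost
bp06	12	translocation	stem_M_pahari	present	1	between_centromere_and_cluster	lost
bp07	4	fission	stem_M_minutoides	present	1	distal_end_of_cluster	lost
bp08	14	fusion	stem_M_musculoides	present	1	distal_end_of_cluster	lost
bp09	1p	fission	stem_Nannomys	unknown	1	NA	NA
bp10	2p	fusion	within_Nannomys	unknown	1	NA	NA
bp11	3	translocation	stem_M_pahari	unknown	1	NA	NA
bp12	5p	fission	stem_M_plathytrix	unknown	1	NA	NA
bp13	9	inversion	within_Coelomys	unknown	1	NA	NA
bp14	11p	fusion	stem_Nannomys	unknown	1	NA	NA
bp15	13p	fission	within_Nannomys	unknown	1	NA	NA
bp16	15p	fusion	stem_M_minutoides	unknown	1	NA	NA
bp17	16	inversion	stem_M_haussa	unknown	1	NA	NA
bp18	1d	fission	stem_Nannomys	absent	0	NA	NA
bp19	2d	fission	within_Nannomys	absent	0	NA	NA
bp20	5d	fusion	stem_Nannomys	absent	0	NA	NA
bp21	5m	fission	stem_M_plathytrix	absent	0	NA	NA
bp22	8d	translocation	within_Nannomys	absent	0	NA	NA
bp23	10d	fission	stem_Nannomys	absent	0	NA	NA
bp24	10d	inversion	stem_M_plathytrix	absent	0	NA	NA
bp25	11d	fission	within_Nannomys	absent	0	NA	NA
bp26	12d	fusion	stem_Nannomys	absent	0	NA	NA
bp27	13d	fission	stem_M_musculoides	absent	0	NA	NA
bp28	15d	translocation	stem_M_minutoides	absent	0	NA	NA
bp29	17d	fission	within_Nannomys	absent	0	NA	NA
bp30	12d	inversion	stem_M_plathytrix	absent	0	NA	NA
bp31	7	fusion	stem_Nannomys	absent	1	NA	NA
bp32	10p	fission	within_Nannomys	absent	1	NA	NA
bp33	18	inversion	stem_M_musculoides	absent	1	NA	NA
bp34	1p	fusion	stem_M_minutoides	absent	1	NA	NA
bp35	2p	fission	stem_M_pahari	absent	1	NA	NA
bp36	3	fusion	within_Coelomys	absent	1	NA	NA
bp37	9	fission	stem_Nannomys	absent	1	NA	NA
bp38	11p	inversion	within_Nannomys	absent	1	NA	NA
bp39	16	fusion	stem_M_musculoides	absent	1	NA	NA
bp40	5p	translocation	stem_M_pahari	absent	1	NA	NA
bp41	15d	fission	stem_Apodemus	present	0	NA	NA
bp42	13d	translocation	stem_Apodemus	present	0	NA	NA
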