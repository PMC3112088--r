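nomenclature	chromosome	proximal_segment	distal_segment
house_mouse	1	1p	1d
house_mouse	2	2p	2d
house_mouse	3	3	3
house_mouse	4	4	4
house_mouse	5	5p	5d
house_mouse	6	6	6
house_mouse	7	7	7
house_mouse	8	8p	8d
house_mouse	9	9	9
house_mouse	10	10p	10d
house_mouse	11	11p	11d
house_mouse	12	12	12d
house_mouse	13	13p	13d
house_mouse	14	14	14
house_mouse	15	15p	15d
house_mouse	16	16	16
house_mouse	17	17p	17d
house_mouse	18	18	18
house_mouse	19	19	19
nannomys	1	1p	NA
nannomys	2	2p	NA
nannomys	3	3	NA
nannomys	4	4	NA
nannomys	5	5p	NA
nannomys	6	6	NA
nannomys	7	7	NA
nannomys	8	8p	NA
nannomys	9	9	NA
nannomys	10	10p	NA
nannomys	11	11p	NA
nannomys	12	12	NA
nannomys	13	13p	NA
nannomys	14	14	NA
nannomys	15	15p	NA
nannomys	16	16	NA
nannomys	17	17p	NA
nannomys	18	18	NA
coelomys	1	1p	NA
coelomys	2	1d	NA
coelomys	3	2p	NA
coelomys	4	2d	NA
coelomys	5	3	NA
coelomys	6	10d	NA
coelomys	7	4	NA
coelomys	8	5p	NA
coelomys	9	12d	NA
coelomys	10	5m	NA
coelomys	11	5d	NA
coelomys	12	6	NA
coelomys	13	7	NA
coelomys	14	8p	NA
coelomys	15	8d	NA
coelomys	16	9	NA
coelomys	17	10p	NA
coelomys	18	11p	NA
coelomys	19	11d	NA
coelomys	20	12	NA
coelomys	21	13d	NA
coelomys	22	15d	NA
coelomys	23	17d	NA
pyromys	5	5p	NA
pyromys	8	8p	NA
pyromys	12	12	NA
rattus	5	5p	NA
rattus	8	8p	NA
rattus	16	16	NA
apodemus	7	NA	2d
apodemus	8	NA	5d
apodemus	11	NA	8d
apodemus	12	NA	12d
apodemus	15	NA	11d
apodemus	16	NA	13d
apodemus	21	NA	15d
apodemus	22	NA	17d
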