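taxon	subgenus	nomenclature	n2
Rattus_rattus	outgroup	rattus	38
Apodemus_sylvaticus	outgroup	apodemus	48
M_pahari	Coelomys	coelomys	48
M_plathytrix	Pyromys	pyromys	26
M_mattheyi	Nannomys	nannomys	36
M_musculoides	Nannomys	nannomys	18
M_minutoides	Nannomys	nannomys	18
M_indutus	Nannomys	nannomys	36
M_haussa	Nannomys	nannomys	36
M_caroli	Mus	house_mouse	40
M_cervicolor	Mus	house_mouse	40
M_cooki	Mus	house_mouse	40
M_fragilicauda	Mus	house_mouse	40
M_famulus	Mus	house_mouse	40
M_spicilegus	Mus	house_mouse	40
M_spretus	Mus	house_mouse	40
M_macedonicus	Mus	house_mouse	40
M_cypriacus	Mus	house_mouse	40
M_m_castaneus	Mus	house_mouse	40
M_m_musculus	Mus	house_mouse	40
M_m_domesticus	Mus	house_mouse	40
M_booduga	Mus	house_mouse	40
M_terricolor	Mus	house_mouse	40
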