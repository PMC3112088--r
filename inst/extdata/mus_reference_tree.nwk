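(Rattus_rattus:1.0,(Apodemus_sylvaticus:0.85,(M_pahari:0.6,((M_mattheyi:0.3,(M_haussa:0.22,(M_indutus:0.15,(M_musculoides:0.08,M_minutoides:0.08):0.07):0.07):0.08):0.22,(M_plathytrix:0.45,((M_caroli:0.2,(M_cervicolor:0.12,M_cooki:0.12):0.08):0.1,((M_terricolor:0.22,(M_booduga:0.15,(M_fragilicauda:0.08,M_famulus:0.08):0.07):0.07):0.04,(M_spretus:0.2,(M_spicilegus:0.16,((M_cypriacus:0.06,M_macedonicus:0.06):0.06,(M_m_castaneus:0.03,(M_m_musculus:0.015,M_m_domesticus:0.015):0.015):0.09):0.04):0.04):0.06):0.04):0.15):0.07):0.08):0.25):0.15);
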