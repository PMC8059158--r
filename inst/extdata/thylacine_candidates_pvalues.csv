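species,dataset,C1,p_C1,theta,p_theta
Chrysocyon_brachyurus,total,0.507,0.001,44.4,0.006
Chrysocyon_brachyurus,facial,0.567,0.008,36.2,0.004
Chrysocyon_brachyurus,neurocranial,0.271,0.062,80.7,0.073
Lupulella_adustus,total,0.537,0.002,35.4,0.001
Lupulella_adustus,facial,0.639,0.004,37.6,0.009
Lupulella_adustus,neurocranial,0.196,0.143,116.4,0.201
Lupulella_mesomelas,total,0.524,0.001,46.0,0.006
Lupulella_mesomelas,facial,0.625,0.005,39.6,0.015
Lupulella_mesomelas,neurocranial,0.076,0.420,114.6,0.192
Lycalopex_gymnocercus,total,0.417,0.006,51.7,0.005
Lycalopex_gymnocercus,facial,0.561,0.013,37.1,0.012
Lycalopex_gymnocercus,neurocranial,0.014,0.694,128.1,0.282
Canis_latrans,total,0.452,0.003,41.4,0.001
Canis_latrans,facial,0.305,0.127,42.6,0.020
Canis_latrans,neurocranial,0.384,0.015,107.8,0.171
Lycalopex_culpaeus,total,0.489,0.004,38.1,0.003
Lycalopex_culpaeus,facial,0.376,0.057,38.4,0.008
Lycalopex_culpaeus,neurocranial,0.515,0.004,96.4,0.141
Vulpes_vulpes,total,0.333,0.023,49.3,0.006
Vulpes_vulpes,facial,0.356,0.076,33.5,0.004
Vulpes_vulpes,neurocranial,0.189,0.166,125.5,0.237
Canis_lupus,total,0.201,0.139,43.7,0.004
Canis_lupus,facial,0.236,0.220,51.3,0.032
Canis_lupus,neurocranial,0.318,0.043,72.1,0.051
dingo,total,0.182,0.144,50.0,0.009
dingo,facial,0.305,0.114,47.2,0.020
dingo,neurocranial,0.271,0.082,84.8,0.091
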