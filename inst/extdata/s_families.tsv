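subcategory	pattern
D7/OBP family	\bD7\b|odorant.?binding
Amylase/maltase/chitinase	amylase|maltase|chitinase
Serine proteases	serine protease|trypsin|chymotrypsin
Adenosine deaminase	adenosine deaminase
Phosphatase	salivary phosphatase|acid phosphatase
DNAse	dnase|endonuclease
Salivary immunity related products	salivary (lysozyme|defensin)|pathogen recognition|salivary immun
Antigen 5 family	antigen[ -]?5
Mucins	mucin
Serpin	serpin
30 kDa antigen/Aegyptin	30 ?kda antigen|aegyptin|ge.?rich
6.3 kDa family	6\.3 ?kda
30.5 kDa family	30\.5 ?kda
23.4 kDa family	23\.4 ?kda
41.9 kDa family	41\.9 ?kda
62 kDa family	62 ?kda
Fragment of culicine salivary protein	culicine salivary protein
16.7 kDa family	16\.7 ?kda|cwrp
GQP repeat family	gqp repeat
9.7 kDa family	9\.7 ?kda
4.2 kDa family	4\.2 ?kda
HHI repeat family	hhi repeat
Cys rich family	cys(teine)?.?rich (peptide|family)
7.8 kDa family	7\.8 ?kda
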