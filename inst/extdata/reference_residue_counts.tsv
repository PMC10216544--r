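# Published residue-property composition counts for pooled CDR3 residues
# from a TCR-beta study of lung edema fluid, per clinical group: raw
# residue occurrence counts (times_found) per property group and the
# percentage as printed. The total residue count of each pool equals the
# sum of the two tRNA synthetase class counts (the classes partition all
# residues).
cohort	group	times_found	percent_printed
non_ARDS	Aliphatic	1270	27.46
non_ARDS	Aromatic	734	15.87
non_ARDS	Sulphur	334	7.22
non_ARDS	Basic	322	6.96
non_ARDS	Acidic	786	16.99
non_ARDS	Aliphatic hydroxyl	1005	21.73
non_ARDS	tRNA synthetase class I	1668	36.06
non_ARDS	tRNA synthetase class II	2957	63.94
ARDS	Aliphatic	13491	28.15
ARDS	Aromatic	7858	16.40
ARDS	Sulphur	3461	7.22
ARDS	Basic	2846	5.94
ARDS	Acidic	8228	17.17
ARDS	Aliphatic hydroxyl	10611	22.14
ARDS	tRNA synthetase class I	17360	36.22
ARDS	tRNA synthetase class II	30566	63.78
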