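# Presence/absence of core apoptosis-machinery families across the five
# ancient eukaryotic supergroups and the non-eukaryotic domains.
# 1 = at least one homolog reported in the lineage; see
# apoptosis_evidence.tsv for the supporting organisms per cell.
family	category	Opisthokonta	Amoebozoa	SAR	Excavata	Archaeplastida	Eubacteria	Archaea	Virus
ENDOG	DNase	1	0	1	1	1	1	0	0
ZEN1	DNase	1	0	1	0	1	1	0	0
NUC1	DNase	1	1	1	1	0	1	0	1
Caspase	Protease	1	0	1	0	0	0	0	1
Metacaspase	Protease	1	0	0	0	1	0	0	0
OMI_HTRA_fungal	Protease	1	0	0	0	1	1	0	0
OMI_HTRA_animal	Protease	1	1	1	0	1	1	0	0
AIFM1	AIF	1	1	0	1	0	1	0	0
AIFM2	AIF	1	1	1	1	1	1	0	0
AIFM3	AIF	1	0	0	0	0	1	0	0
NDI1	AIF	1	1	1	1	1	1	0	0
BIR	Inhibitor	1	0	1	1	1	0	0	1
API5	Inhibitor	1	0	0	0	1	0	0	0
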