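# Supporting organisms/lineages behind each present cell of
# apoptosis_presence.tsv.
family	group	evidence
ENDOG	Opisthokonta	Saccharomyces cerevisiae; animals
ENDOG	Excavata	trypanosomes
ENDOG	SAR	Toxoplasma; Reticulomyxa
ENDOG	Archaeplastida	Volvox; Chlamydomonas
ENDOG	Eubacteria	eubacterial members of the ENDOG clade (no archaeal members)
ZEN1	Archaeplastida	plants
ZEN1	Opisthokonta	fungi (Moniliophthora)
ZEN1	SAR	Apicomplexa (Plasmodium)
ZEN1	Eubacteria	eubacterial homologs in the ZEN1 clade
NUC1	Opisthokonta	animals; Saccharomyces cerevisiae
NUC1	SAR	ciliates; Reticulomyxa
NUC1	Excavata	Trichomonas
NUC1	Amoebozoa	Dictyostelium
NUC1	Eubacteria	eubacterial DNase II-domain proteins
NUC1	Virus	viral DNase II-domain proteins
Caspase	Opisthokonta	animals
Caspase	SAR	Reticulomyxa proteases in the caspase clade
Caspase	Virus	viral peptidases related to animal caspases
Metacaspase	Opisthokonta	fungi
Metacaspase	Archaeplastida	plants
OMI_HTRA_fungal	Opisthokonta	Saccharomyces cerevisiae NMA111
OMI_HTRA_fungal	Archaeplastida	chloroplast proteases of Arabidopsis and Chlamydomonas
OMI_HTRA_fungal	Eubacteria	eubacterial serine proteases closer to the fungal branch than to the animal branch
OMI_HTRA_animal	Opisthokonta	human OMI/HTRA; human TYSND1
OMI_HTRA_animal	SAR	Paramecium
OMI_HTRA_animal	Archaeplastida	Arabidopsis
OMI_HTRA_animal	Amoebozoa	Dictyostelium
OMI_HTRA_animal	Eubacteria	eubacterial serine proteases in the animal-type branch
AIFM1	Opisthokonta	Metazoa
AIFM1	Amoebozoa	Dictyostelium
AIFM1	Excavata	Naegleria
AIFM1	Eubacteria	eubacterial members of the AIFM1/AIFM3 branch; shared AIF_C domain architecture
AIFM2	Opisthokonta	human AIFM2
AIFM2	Amoebozoa	Amoebozoa members of the AIFM2 branch
AIFM2	SAR	SAR members of the AIFM2 branch
AIFM2	Excavata	Excavata members of the AIFM2 branch
AIFM2	Archaeplastida	Archaeplastida members of the AIFM2 branch
AIFM2	Eubacteria	eubacterial proteins in the AIFM2 branch
AIFM3	Opisthokonta	human AIFM3
AIFM3	Eubacteria	eubacterial members of the AIFM1/AIFM3 branch; shared Rieske domain architecture
NDI1	Opisthokonta	Saccharomyces cerevisiae NDI1
NDI1	Amoebozoa	Amoebozoa members of the NDI1 branch
NDI1	SAR	SAR members of the NDI1 branch; Tetrahymena AIF
NDI1	Excavata	Excavata members of the NDI1 branch
NDI1	Archaeplastida	Archaeplastida members of the NDI1 branch
NDI1	Eubacteria	eubacterial proteins in the NDI1 branch
BIR	Opisthokonta	survivin/BIR1p of animals and fungi
BIR	SAR	Paramecium tetraurelia A0CYG7
BIR	Excavata	Naegleria gruberi D2UXF5
BIR	Archaeplastida	Guillardia theta L1JDG1
BIR	Virus	viral BIR-domain proteins
API5	Opisthokonta	human AAC11
API5	Archaeplastida	plant API5-like proteins
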