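pattern	element_name	description	source
CACGTG	G-box	G box; binding site for the bHLH transcription factor AtMYC2	curated snapshot
CANNTG	E-box/MYC consensus	MYC recognition consensus (E box) bound by bHLH transcription factors	curated snapshot
CCACGTGG	G-box palindrome	Palindromic extended G box found in light- and ABA-regulated promoters	curated snapshot
CACGTA	ABRE	Abscisic acid-responsive element (ACGT core) bound by ABA-dependent bZIP transcription factors	curated snapshot
ACGT	ACGT element	ACGT core element; desiccation responsive	curated snapshot
TACGTA	A-box	A-box class ACGT element found in the octopine synthase (ocs) promoter	curated snapshot
GTCATA	W-box	W box; binding site for WRKY3 and WRKY6	curated snapshot
TTGACY	W-box consensus	TTGAC(C/T) W box consensus bound by WRKY transcription factors	curated snapshot
ATTATC	GT-1 consensus	Consensus GT-1 binding site found in many light-regulated gene promoters	curated snapshot
ATAGTA	Mem1/CACT module	Component of Mem1 (mesophyll expression module 1) of the ppcA1 phosphoenolpyruvate carboxylase distal regulatory element of Flaveria trinervia	curated snapshot
AATACT	Mem1/CACT module	Component of Mem1 (mesophyll expression module 1) of the ppcA1 phosphoenolpyruvate carboxylase distal regulatory element of Flaveria trinervia	curated snapshot
GTAGTA	Mem1/CACT module	Component of Mem1 (mesophyll expression module 1) of the ppcA1 phosphoenolpyruvate carboxylase distal regulatory element of Flaveria trinervia	curated snapshot
TAAGTA	Mem1/CACT module	Component of Mem1 (mesophyll expression module 1) of the ppcA1 phosphoenolpyruvate carboxylase distal regulatory element of Flaveria trinervia	curated snapshot
AATATT	rolD motif	Motif found in promoters of the root-specific rolD gene of Agrobacterium rhizogenes	curated snapshot
GGCCCA	site II element	Site II element found in promoters of nuclear genes encoding oxidative phosphorylation (cytochrome) components in Arabidopsis and rice	curated snapshot
GTAC	CuRE core	GTAC core of the copper-response element (CuRE) of Chlamydomonas Cyc6 and Cpx1; involved in their oxygen response	curated snapshot
CTAATA	cytokinin POR element	Sequence critical for cytokinin-enhanced protein binding in the cucumber POR (NADPH-protochlorophyllide reductase) promoter	curated snapshot
CAAT	CAAT consensus	CAAT promoter consensus sequence found in the legA storage-protein gene of pea	curated snapshot
WAACCA	MYB recognition site	MYB recognition element found in dehydration-responsive promoters	curated snapshot
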