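motif	cluster	k_fg	K_fg	n_bg	N_bg	expected_enrichment
CACGTG	up	128	849	3824	34417	1.35692989
CACGTA	up	212	849	6883	34417	1.24860024
ACGTAT	up	247	849	8196	34417	1.22168805
ACGTAA	up	280	849	9370	34417	1.21138938
ACGTGA	up	224	849	7661	34417	1.18529889
GTCATA	up	373	849	13259	34417	1.14041621
ATTATC	up	600	849	21924	34417	1.10942201
ATAGTA	up	564	849	20635	34417	1.10800049
AATACT	up	596	849	21847	34417	1.10590997
AATATT	up	736	849	27066	34417	1.10234886
GGCCCA	down	110	631	3947	34417	1.52008968
AGTACT	down	170	631	6900	34417	1.34382737
TACGTA	down	118	631	5002	34417	1.28671384
GTACTA	down	235	631	10009	34417	1.28062161
ACGTAA	down	209	631	9370	34417	1.2166071
GTAGTA	down	238	631	11059	34417	1.17382878
CTAATA	down	435	631	20787	34417	1.14140848
TAAGTA	down	409	631	19684	34417	1.13332274
ATAGTA	down	426	631	20635	34417	1.12602693
CAATTA	down	484	631	23958	34417	1.10189054
ACAATA	down	487	631	24128	34417	1.10090866
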