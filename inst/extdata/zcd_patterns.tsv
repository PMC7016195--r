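# Bundled consensus patterns for the P2X7 ballast / ZCD analysis.
# Notation: uppercase letter = exact residue; (A/B) or trailing A/B = residue class;
# x = one wildcard, xN = N wildcards. See ?parse_pattern.
name	notation	description
cluster1	PxWCxCx2C	ZCD cysteine cluster 1 (3 Zn-coordinating cysteines)
cluster2	LCCRx3GxCITTS/T	ZCD cysteine cluster 2 (3 Zn-coordinating cysteines; ends in the ITTS beta-arrestin site)
cluster3	(L/I/V)PSC(C/S)x3IRx2(F/Y)Px5Y(S/T)G	ZCD cysteine cluster 3 (1 obligate + 1 optional cysteine; carries R578, F/Y581-P582 and the terminal Y-S/T-G)
ccys_anchor_full	SNCCRSHIYPWCKCCQPC	full mammalian C-cys anchor, 18 residues (rat 360-377); palmitoylated S/C sites
ccys_core	SxxCC	most-conserved initial core of the C-cys anchor
ccys_teleost	LIGTGCYSK	teleost single-cysteine context at the C-cys anchor position
ccys_gar	FITTYLYPRCCAR	spotted-gar variant of the C-cys anchor region
gdp_rh_block	R(H/Y)x2Yx8WRF	conserved block between the clusters: R546-H547 (H sometimes Y), Y550, and the WRF motif
gdp_rh	R(H/Y)	proximal GDP-site pair R546-H547 alone (fallback when the full block is degraded)
gdp_rk	Rx3Rx4K	distal GDP-site basic residues R574-R578-K583 (subscript spacing)
wrf	WRF	WRF motif between the GDP-site halves
lps_wrirg	WRIRx5G	LPS-binding-like consensus conserved across P2X7
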