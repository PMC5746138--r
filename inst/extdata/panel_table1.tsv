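gene_name	role	chemistry
ACTG1	marker	mRNA
AMFR	marker	mRNA
ASNS	marker	mRNA
ATP7B	marker	mRNA
BAMBI	marker	mRNA
BCL2L1	marker	mRNA
CASP6	marker	mRNA
CDC2	marker	mRNA
CDH1	marker	mRNA
CDH3	marker	mRNA
18S-rRNA	internal_control	mRNA
CEACAM7	marker	mRNA
CLDN1	marker	mRNA
CLDN3	marker	mRNA
CLDN4	marker	mRNA
CLDN9	marker	mRNA
CLK1	marker	mRNA
CTGF	marker	mRNA
CTSC	marker	mRNA
CTSE	marker	mRNA
CYB561	marker	mRNA
DUSP3	marker	mRNA
DUSP8	marker	mRNA
E2F1	marker	mRNA
EGFR	marker	mRNA
ELA3A,ELA3B	marker	mRNA
EPCAM	marker	mRNA
F3	marker	mRNA
FGF2	marker	mRNA
GPR68	marker	mRNA
GRB10	marker	mRNA
GSTA2	marker	mRNA
HMGN2	marker	mRNA
HSF2	marker	mRNA
HSP90B1	marker	mRNA
IL6	marker	mRNA
ILKAP	marker	mRNA
INPPL1	marker	mRNA
KLRB1	marker	mRNA
KRT17	marker	mRNA
KRT7	marker	mRNA
LDHA	marker	mRNA
MAD2L1	marker	mRNA
MAP2K4	marker	mRNA
MMP2	marker	mRNA
MUC3A,MUC3B	marker	mRNA
MYC	marker	mRNA
NFATC1	marker	mRNA
PHLDA1	marker	mRNA
PPP1R1A	marker	mRNA
PPP2R5C	marker	mRNA
PTGFR	marker	mRNA
PVRL1	marker	mRNA
RAF1	marker	mRNA
RHOBTB3	marker	mRNA
SDC1	marker	mRNA
SERPIND1	marker	mRNA
SH3BP1	marker	mRNA
SLC19A1	marker	mRNA
SMARCA1	marker	mRNA
SPARC	marker	mRNA
STC1	marker	mRNA
TF	marker	mRNA
TGIF1	marker	mRNA
TJP3	marker	mRNA
TNC	marker	mRNA
TNFAIP3	marker	mRNA
TP53	marker	mRNA
USP12	marker	mRNA
VIM	marker	mRNA
ZNF91	marker	mRNA
TMPRSS4	marker	mRNA
MST1R	marker	mRNA
NT5E	marker	mRNA
RALB	marker	mRNA
TRIO	marker	mRNA
EZH2	marker	mRNA
MELK	marker	mRNA
PAK4	marker	mRNA
RRAS	marker	mRNA
RPLP0	reference	mRNA
PPIA	reference	mRNA
RPL37A	reference	mRNA
RPL30	reference	mRNA
RPS17	reference	mRNA
hsa-mir-1246	marker	miRNA
hsa-mir-135b	marker	miRNA
hsa-mir-196a	marker	miRNA
hsa-mir-210	marker	miRNA
hsa-miR-217	marker	miRNA
hsa-miR-155	marker	miRNA
hsa-miR-203	marker	miRNA
hsa-miR-148a	marker	miRNA
hsa-miR-375	marker	miRNA
RNU44	reference	miRNA
RNU48	reference	miRNA
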