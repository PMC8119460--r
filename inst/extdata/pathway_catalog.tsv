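gene	pathways
ABCA1	FDA
ABCG5	FDA
ACE2	PDA
AGPAT1	FDA
AGPAT2	FDA
APOA1	FDA
APOA4	FDA
APOB	FDA
ATP1B3	CDA;PDA
ATP1B4	CDA
CACNA1D	CDA
CD36	FDA
CEL	FDA
CELA3B	PDA
CPB1	PDA
CTRL	PDA
DPP4	PDA
FABP1	FDA
GOT2	FDA
HK3	CDA
HKDC1	CDA
LCT	CDA
MEP1A	PDA
MEP1B	PDA
MME	PDA
MTTP	FDA
NPC1L1	FDA
PIK3CB	CDA
SCARB1	FDA
SI	CDA
SLC15A1	PDA
SLC27A4	FDA
SLC2A5	CDA
SLC36A1	PDA
SLC37A4	CDA
SLC5A1	CDA
XPNPEP2	PDA
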