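attribute	group1	group2	group3
hydrophobicity	RKEDQN	GASTPHY	CLVIMFW
normwaalsvolume	GASCTPD	NVEQIL	MHKFRYW
polarity	LIFWCMVY	PATGS	HQRKNED
polarizability	GASDT	CPNVEQIL	KMHFRYW
charge	KR	ANCQGHILMFPSTWYV	DE
secondarystruct	EALMQKRH	VIYCWFT	GNPSD
solventaccess	ALFCGIVW	RKQEND	MSPTHY
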