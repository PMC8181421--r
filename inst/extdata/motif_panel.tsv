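name	consensus
ETS	CAGGAAGT
RUNX	TGYGGT
AP-1	TGASTCA
TCF/LEF	CTTTGWW
NFAT	TGGAAA
T-box	AGGTGTGA
EGR	GCGBGGGCG
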