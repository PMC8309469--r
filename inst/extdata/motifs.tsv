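# promoter hexamer boxes: W-box (WRKY) and the ACGT-core bZIP boxes
name	pattern
W-box	YTGACY
A-box	TACGTA
T-box	AACGTT
C-box	GACGTA
G-box	CACGTA
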