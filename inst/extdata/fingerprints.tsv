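name	pattern
G1	GxxxxGK[ST]
G3	DxxG
G4	[NT]KxD
FYVE_CORE	RRHHCRxCG
PX_CORE	RR[FY]SDF
CXXC	CxxC
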