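cytokine_signaling	synthetic neuroinflammation gene sets	TNF	IL4	IL1B	NFKB1	CCR2	PTGS2
insulin_signaling	synthetic neuroinflammation gene sets	INS	PDPK1	AKT1	PRKAA1	GSK3B	TSC2
autophagy_regulation	synthetic neuroinflammation gene sets	MTOR	TSC2	RHEB	PRKAA1	BACE1
tau_pathology	synthetic neuroinflammation gene sets	GSK3B	MAPT	APP
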