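human_symbol	mouse_symbol
PTGS2	Ptgs2
PDPK1	Pdpk1
AKT1	Akt1
TSC2	Tsc2
MTOR	Mtor
RHEB	Rheb
INS	Ins
IL4	Il4
TNF	Tnf
NFKB1	Nfkb1
GSK3B	Gsk3b
MAPT	Mapt
BACE1	Bace1
CCR2	Ccr2
PRKAA1	Prkaa1
IL1B	Il1b
APP	App
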