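subject_function	subject_ns	subject_id	subject_mod	relation	object_function	object_ns	object_id	object_mod	species	citation	evidence
protein	MGI	Pdpk1		increases	protein	MGI	Il4	act	mouse	ref031	Pdpk1 increases the activity of Il4 in normal conditions
protein	MGI	Pdpk1		increases	protein	MGI	Ins	act	mouse	ref031	Pdpk1 increases the activity of Ins in normal conditions
protein	MGI	Pdpk1		increases	protein	MGI	Akt1	pmod(P)	mouse	ref032	Pdpk1 phosphorylates Akt1
protein	MGI	Pdpk1		increases	protein	MGI	Gsk3b	pmod(P)	mouse	ref032	Pdpk1 phosphorylates Gsk3b
protein	MGI	Pdpk1		decreases	protein	MGI	Ccr2		mouse	ref031	Pdpk1 inhibits Ccr2
protein	MGI	Pdpk1		decreases	cell_population	MESH	M1 macrophage		mouse	ref031	Pdpk1 inhibits M1 macrophages
protein	MGI	Pdpk1		decreases	bioprocess	GOBP	insulin resistance		mouse	ref031	Pdpk1 inhibits insulin resistance
protein	MGI	Ptgs2		increases	chemical	CHEBI	amyloid-beta		mouse	ref033	Ptgs2 increases amyloid-beta peptides
chemical	CHEBI	amyloid-beta		increases	protein	MGI	Tnf		mouse	ref035	amyloid-beta increases Tnf
chemical	CHEBI	amyloid-beta		increases	protein	MGI	Nfkb1		mouse	ref035	amyloid-beta increases Nfkb1
protein	MGI	Nfkb1		increases	protein	MGI	Ptgs2		mouse	ref036	Nfkb1 increases Ptgs2 forming a self-regulatory loop
protein	MGI	Tnf		increases	bioprocess	GOBP	inflammatory response		mouse	ref036	increased Tnf activation increases inflammation
cell_population	MESH	M1 macrophage		increases	bioprocess	GOBP	phagocytosis		mouse	ref031	M1 macrophages increase phagocytosis
protein	MGI	Ccr2		increases	bioprocess	GOBP	amyloid-beta clearance		mouse	ref031	Ccr2 increases amyloid-beta clearance
protein	MGI	Gsk3b		increases	protein	MGI	Mapt	pmod(P)	mouse	ref032	Gsk3b phosphorylates tau
protein	MGI	Mapt		increases	bioprocess	GOBP	neurofibrillary tangle formation		mouse	ref032	phosphorylated tau drives neurofibrillary tangle formation
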