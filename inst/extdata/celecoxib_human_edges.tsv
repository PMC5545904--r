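subject_function	subject_ns	subject_id	subject_mod	relation	object_function	object_ns	object_id	object_mod	species	citation	evidence
protein	HGNC	PDPK1		increases	protein	HGNC	AKT1	pmod(P)	human	ref037	PDPK1 sustains AKT1 phosphorylation in normal physiology
protein	HGNC	AKT1		decreases	protein	HGNC	TSC2	pmod(P)	human	ref037	reduced AKT1 phosphorylation increases TSC2 phosphorylation at Thr1462
protein	HGNC	TSC2		increases	protein	HGNC	RHEB		human	ref039	hyperphosphorylated TSC2 acts through RHEB
protein	HGNC	RHEB		increases	protein	HGNC	MTOR		human	ref039	RHEB hyperactivates MTOR
protein	HGNC	MTOR		decreases	bioprocess	GOBP	autophagy		human	ref039	MTOR hyperactivation reduces autophagy
bioprocess	GOBP	autophagy		decreases	bioprocess	GOBP	amyloid-beta deposition		human	ref039	reduced autophagy leads to increased amyloid deposition
protein	HGNC	MTOR		increases	protein	HGNC	BACE1		human	ref041	decreased MTOR activity is needed to decrease BACE1
protein	HGNC	BACE1		increases	chemical	CHEBI	amyloid-beta		human	ref041	BACE1 drives amyloid-beta generation
protein	HGNC	PDPK1		increases	protein	HGNC	IL4	act	human	ref043	PDPK1 sustains anti-inflammatory IL-4
protein	HGNC	IL4		decreases	bioprocess	GOBP	inflammatory response		human	ref043	IL-4 is anti-inflammatory; its inhibition causes inflammation
protein	HGNC	PDPK1		increases	protein	HGNC	INS	act	human	ref044	PDPK1 sustains INS
protein	HGNC	INS		decreases	bioprocess	GOBP	insulin resistance		human	ref044	INS inhibition increases insulin resistance
protein	HGNC	PTGS2		increases	chemical	CHEBI	amyloid-beta		human	ref033	PTGS2 increases amyloid-beta peptides
protein	HGNC	PDPK1		increases	protein	HGNC	PRKAA1	pmod(P)	human	ref045	PDPK1 phosphorylates AMPK (PRKAA1)
protein	HGNC	PRKAA1		decreases	protein	HGNC	MTOR		human	ref045	AMPK reduces MTOR activation in normal physiology
bioprocess	GOBP	autophagy		increases	bioprocess	GOBP	amyloid-beta clearance		human	ref045	autophagy sustains amyloid-beta clearance
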