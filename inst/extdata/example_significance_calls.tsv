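gene	study_id	criterion	significant
TNFSF10	RA1	top_k	TRUE
TNFSF10	RA2	top_k	TRUE
TNFSF10	SLE1	top_k	TRUE
TNFSF10	SLE2	top_k	TRUE
TNFSF10	OA	top_k	FALSE
TNFSF10	AS	top_k	TRUE
LY96	RA1	top_k	TRUE
LY96	RA2	top_k	FALSE
LY96	SLE1	top_k	FALSE
LY96	SLE2	top_k	TRUE
LY96	OA	top_k	FALSE
LY96	AS	top_k	TRUE
PRKCH	RA1	top_k	TRUE
PRKCH	RA2	top_k	FALSE
PRKCH	SLE1	top_k	FALSE
PRKCH	SLE2	top_k	FALSE
PRKCH	OA	top_k	TRUE
PRKCH	AS	top_k	TRUE
TXN	RA1	top_k	TRUE
TXN	RA2	top_k	FALSE
TXN	SLE1	top_k	FALSE
TXN	SLE2	top_k	TRUE
TXN	OA	top_k	FALSE
TXN	AS	top_k	TRUE
CX3CR1	RA1	top_k	FALSE
CX3CR1	RA2	top_k	TRUE
CX3CR1	SLE1	top_k	FALSE
CX3CR1	SLE2	top_k	FALSE
CX3CR1	OA	top_k	TRUE
CX3CR1	AS	top_k	TRUE
TXN	RA1	fdr	TRUE
TXN	RA2	fdr	FALSE
TXN	SLE1	fdr	FALSE
TXN	SLE2	fdr	TRUE
TXN	OA	fdr	FALSE
TXN	AS	fdr	TRUE
CX3CR1	RA1	fdr	FALSE
CX3CR1	RA2	fdr	TRUE
CX3CR1	SLE1	fdr	FALSE
CX3CR1	SLE2	fdr	FALSE
CX3CR1	OA	fdr	TRUE
CX3CR1	AS	fdr	TRUE
TLR5	RA1	fdr	FALSE
TLR5	RA2	fdr	TRUE
TLR5	SLE1	fdr	FALSE
TLR5	SLE2	fdr	TRUE
TLR5	OA	fdr	TRUE
TLR5	AS	fdr	FALSE
TIA1	RA1	fdr	FALSE
TIA1	RA2	fdr	TRUE
TIA1	SLE1	fdr	FALSE
TIA1	SLE2	fdr	TRUE
TIA1	OA	fdr	TRUE
TIA1	AS	fdr	FALSE
PRF1	RA1	fdr	FALSE
PRF1	RA2	fdr	TRUE
PRF1	SLE1	fdr	FALSE
PRF1	SLE2	fdr	TRUE
PRF1	OA	fdr	TRUE
PRF1	AS	fdr	FALSE
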