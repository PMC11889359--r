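accession	gene	group
P29317	EPHA2	TK
P54760	EPHB4	TK
P54764	EPHA4	TK
P54762	EPHB1	TK
Q16288	NTRK3	TK
Q08345	DDR1	TK
P07948	LYN	TK
P12931	SRC	TK
P23458	JAK1	TK
O60674	JAK2	TK
O14976	GAK	Other
Q99683	MAP3K5	STE
O95382	MAP3K6	STE
Q6ZN16	MAP3K15	STE
Q9NYL2	MAP3K20	STE
P00533	EGFR	TK
P06239	LCK	TK
P17612	PRKACA	AGC
P28482	MAPK1	CMGC
P24941	CDK2	CMGC
Q05397	PTK2	TK
P49840	GSK3A	CMGC
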